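# Density-matrix propagation.  States are complex 2^n x 2^n matrices in the
# product basis of sys$spins; ensembles are lists of such matrices, one per
# spatial slice.

#' Evolve a density matrix under a static Hamiltonian
#'
#' Unitary evolution `exp(-iHt) rho exp(+iHt)` followed by phenomenological
#' relaxation: every coherence `rho[a, b]` decays at the sum of `1/T2`
#' over the spins whose basis state differs between `a` and `b` (so a
#' single-quantum coherence of spin `i` decays at `1/T2_i`), and the
#' population deviation from thermal equilibrium decays at the mean `1/T1`
#' of the spins that declare a T1 (populations are frozen when no spin
#' does).  The trace is preserved exactly.
#'
#' @param rho Density matrix.
#' @param H Hamiltonian (rad/s), must be Hermitian.
#' @param duration Evolution time (s), non-negative.
#' @param sys The [spin_system()]; supplies relaxation times.  With
#'   `relax = FALSE` (or `sys = NULL`) evolution is purely unitary.
#' @param relax Apply relaxation?
#' @return The evolved density matrix.
#' @export
propagate <- function(rho, H, duration, sys = NULL, relax = TRUE) {
  if (duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(rho)
  nrmH <- max(abs(H))
  if (nrmH > 0 && max(abs(H - Conj(t(H)))) > 1e-10 * nrmH)
    stop("Hamiltonian must be Hermitian")
  e <- eigen(H)
  U <- propagator_from_eigen(list(values = Re(e$values), vectors = e$vectors),
                             duration)
  rho <- U %*% rho %*% Conj(t(U))
  if (relax && !is.null(sys)) rho <- apply_relaxation(rho, sys, duration)
  rho
}

apply_relaxation <- function(rho, sys, duration) {
  rr <- relaxation_rates(sys)
  if (all(rr$R2 == 0) && rr$r1bar == 0) return(rho)
  d0 <- diag(rho)
  rho <- rho * exp(-rr$R2 * duration)
  if (rr$r1bar > 0) {
    eq <- sys$cache[["eq_diag"]]
    if (is.null(eq)) {
      eq <- Re(diag(equilibrium_state(sys)))
      sys$cache[["eq_diag"]] <- eq
    }
    diag(rho) <- eq + (d0 - eq) * exp(-rr$r1bar * duration)
  } else {
    diag(rho) <- d0
  }
  rho
}

# Fast path used by the engine: cached eigen-decomposition.
propagate_cached <- function(rho, sys, duration, relax = TRUE,
                             coupling_mode = "heteronuclear_secular") {
  if (duration == 0) return(rho)
  U <- propagator_from_eigen(ham_eigen(sys, coupling_mode), duration)
  rho <- U %*% rho %*% Conj(t(U))
  if (relax) rho <- apply_relaxation(rho, sys, duration)
  rho
}

#' Apply an instantaneous hard pulse
#'
#' Rotation `exp(-i flip * sum_i I_i,phase)` over all spins of the chosen
#' isotope.  With this sign convention a 90 degree x pulse takes `Iz` to
#' `-Iy`.
#'
#' @param rho Density matrix.
#' @param sys The [spin_system()].
#' @param isotope Channel.
#' @param flip Flip angle (degrees).
#' @param phase Pulse phase (degrees, 0 = x).
#' @return The rotated density matrix.
#' @export
apply_hard_pulse <- function(rho, sys, isotope = "H1", flip = 90, phase = 0) {
  U <- hard_pulse_propagator(sys, isotope, flip, phase)
  U %*% rho %*% Conj(t(U))
}

hard_pulse_propagator <- function(sys, isotope, flip, phase, spins = NULL) {
  key <- sprintf("hp_%s_%.9g_%.9g_%s", isotope, flip, phase,
                 paste(spins, collapse = "."))
  cached <- sys$cache[[key]]
  if (!is.null(cached)) return(cached)
  idx <- if (is.null(spins)) isotope_indices(sys, isotope)
         else spin_index(sys, spins)
  if (!length(idx)) {
    U <- diag(2^n_spins(sys))
  } else {
    ph <- phase * pi / 180
    G <- cos(ph) * total_operator(sys, idx, "x") +
      sin(ph) * total_operator(sys, idx, "y")
    U <- rotation_operator(G, flip * pi / 180)
  }
  sys$cache[[key]] <- U
  U
}

# z-rotation of all spins of an isotope by `deg` degrees (used to phase-shift
# cached shaped-pulse propagators).
z_rotation_propagator <- function(sys, isotope, deg) {
  idx <- isotope_indices(sys, isotope)
  G <- total_operator(sys, idx, "z")
  rotation_operator(G, deg * pi / 180)
}

#' Apply a shaped (amplitude/phase modulated) pulse
#'
#' The pulse is integrated as a product of piecewise-constant propagators,
#' one per waveform sample, each including the free-evolution Hamiltonian.
#' A transmitter `offset` is realised as a frequency-modulated phase ramp,
#' i.e. the pulse stays phase coherent with the rotating frame rather than
#' jumping the frame.
#'
#' @inheritParams apply_hard_pulse
#' @param shape A [pulse_shape()].
#' @param duration Pulse length (s).
#' @param peak_b1 Peak RF amplitude (Hz).
#' @param offset Offset of the pulse centre frequency from the carrier (Hz).
#' @param relax Apply relaxation over the pulse duration.
#' @return The evolved density matrix.
#' @export
apply_shaped_pulse <- function(rho, sys, shape, duration, peak_b1,
                               offset = 0, phase = 0, isotope = "H1",
                               relax = TRUE) {
  U <- shaped_pulse_propagator(sys, shape, duration, peak_b1, offset,
                               phase, isotope)
  rho <- U %*% rho %*% Conj(t(U))
  if (relax) rho <- apply_relaxation(rho, sys, duration)
  rho
}

shaped_pulse_propagator <- function(sys, shape, duration, peak_b1,
                                    offset = 0, phase = 0, isotope = "H1") {
  if (duration <= 0) stop("shaped pulse duration must be > 0")
  amps <- shape$samples$amplitude
  phs <- shape$samples$phase
  ns <- length(amps)
  if (ns < 32) stop("shape must have at least 32 samples")
  key <- sprintf("sp_%s_%s_%.9g_%.9g_%.9g", shape$name, isotope,
                 duration, peak_b1, offset)
  U0 <- sys$cache[[key]]
  if (is.null(U0)) {
    dt <- duration / ns
    tmid <- (seq_len(ns) - 0.5) * dt
    idx <- isotope_indices(sys, isotope)
    Ix <- total_operator(sys, idx, "x")
    Iy <- total_operator(sys, idx, "y")
    H0 <- free_hamiltonian(sys)
    U0 <- diag(2^n_spins(sys))
    for (k in seq_len(ns)) {
      # offset as a centre-referenced phase ramp: the net propagator of a
      # refocusing pulse is then a rotation about a fixed transverse axis
      phk <- phs[k] * pi / 180 + 2 * pi * offset * (tmid[k] - duration / 2)
      Hk <- H0 + 2 * pi * peak_b1 * amps[k] * (cos(phk) * Ix + sin(phk) * Iy)
      e <- eigen(Hk)
      U0 <- propagator_from_eigen(
        list(values = Re(e$values), vectors = e$vectors), dt) %*% U0
    }
    sys$cache[[key]] <- U0
  }
  if (phase == 0) return(U0)
  Rz <- z_rotation_propagator(sys, isotope, phase)
  Rz %*% U0 %*% Conj(t(Rz))
}

#' Apply a pulsed field gradient to an ensemble of states
#'
#' Slice `k` at position `z[k]` acquires a phase
#' `gamma_i * amplitude * z[k] * duration` on each single-quantum coherence
#' of spin `i` (proportional to coherence order in general); z
#' magnetization is unaffected.  Free evolution during the gradient is not
#' included here; [run_sequence()] adds it separately.
#'
#' @param rhos List of density matrices, one per slice.
#' @param sys The [spin_system()].
#' @param z Slice positions (cm).
#' @param amplitude Gradient amplitude (G/cm).
#' @param duration Gradient length (s).
#' @return List of dephased density matrices.
#' @export
apply_gradient <- function(rhos, sys, z, amplitude, duration) {
  stopifnot(length(rhos) == length(z))
  if (amplitude == 0 || duration == 0) return(rhos)
  gam <- GAMMA[sys$spins$isotope]
  lab <- sys$spins$label
  n <- n_spins(sys)
  # diagonal of sum_i gamma_i I_iz in the product basis
  mz <- rep(0, 2^n)
  for (i in seq_len(n))
    mz <- mz + gam[i] * Re(diag(single_spin_operator(sys, lab[i], "z")))
  lapply(seq_along(rhos), function(k) {
    ph <- exp(-1i * mz * amplitude * z[k] * duration)
    rhos[[k]] * (ph %o% Conj(ph))
  })
}

#' Acquire one chunk of data from a single state
#'
#' Samples the expectation value of the summed raising operator of the
#' observed channel at dwell intervals, propagating (with relaxation and
#' optional ideal heteronuclear decoupling) between samples.  Optionally
#' adds seeded complex white Gaussian noise.
#'
#' @inheritParams apply_hard_pulse
#' @param n_points Number of complex samples.
#' @param dwell Dwell time (s).
#' @param channel Observed isotope.
#' @param decouple Zero heteronuclear couplings during the chunk.
#' @param noise_sigma Standard deviation of the complex Gaussian noise added
#'   to each sample (per quadrature).
#' @param seed Optional RNG seed for the noise.
#' @return List with `samples` (complex vector) and `state` (the density
#'   matrix after the chunk).
#' @export
acquire_chunk <- function(rho, sys, n_points, dwell, channel = "H1",
                          decouple = TRUE, noise_sigma = 0, seed = NULL) {
  stopifnot(n_points >= 1, dwell > 0)
  asys <- if (decouple) set_heteronuclear_decoupling(sys, TRUE) else sys
  D <- detection_operator(asys, channel)
  tD <- t(D)
  U <- propagator_from_eigen(ham_eigen(asys), dwell)
  Uh <- Conj(t(U))
  s <- complex(n_points)
  for (k in seq_len(n_points)) {
    s[k] <- sum(rho * tD)
    rho <- U %*% rho %*% Uh
    rho <- apply_relaxation(rho, asys, dwell)
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex(real = stats::rnorm(n_points, 0, noise_sigma),
                     imaginary = stats::rnorm(n_points, 0, noise_sigma))
  }
  list(samples = s, state = rho)
}

resolve_phase <- function(ev, phase_cycle, step) {
  ph <- ev$phase %||% 0
  if (!is.null(ev$phase_table)) {
    tab <- phase_cycle$tables[[ev$phase_table]]
    if (is.null(tab)) stop("unresolved phase table: ", ev$phase_table)
    ph <- ph + tab[(step - 1L) %% length(tab) + 1L]
  }
  ph
}

#' Run a pulse-sequence plan
#'
#' Executes an event list for each phase-cycle step, sums receiver-phased
#' signals, and returns the acquired chunks.  Gradients act over a spatial
#' ensemble of density matrices; a classical water magnetization (see
#' [water_model()]) is co-evolved and added to the receiver but does not
#' couple back into the quantum system.
#'
#' @param sys A [spin_system()].
#' @param events List of events (see [events]).
#' @param ensemble An [ensemble_config()]; a single slice is used when the
#'   plan contains no gradient events.
#' @param phase_cycle List with `tables` (named list of phase vectors,
#'   degrees) and `receiver` (vector of receiver phases, degrees, one per
#'   step); `NULL` runs a single step.
#' @param water Optional [water_model()].
#' @param init Optional initial density matrix, or a function of `sys`
#'   returning one; defaults to thermal equilibrium.
#' @param noise_sigma Complex Gaussian noise s.d. added per acquired point.
#' @param seed RNG seed used for noise injection (recorded in the result).
#' @param relax Apply relaxation.
#' @param return_state Also return the final per-slice density matrices of
#'   the last phase step.
#' @return A `chunked_fid` object: per-chunk complex vectors plus dwell,
#'   chunk size and `sw_ps` (the chunk repetition rate `1/(chunk duration)`)
#'   metadata.
#' @export
run_sequence <- function(sys, events, ensemble = ensemble_config(),
                         phase_cycle = NULL, water = NULL, init = NULL,
                         noise_sigma = 0, seed = NULL, relax = TRUE,
                         return_state = FALSE) {
  has_grad <- any(vapply(events, function(e)
    e$kind == "gradient" && e$amplitude != 0, logical(1)))
  z <- if (has_grad) ensemble$z else 0
  nsl <- length(z)
  if (has_grad) {
    bad <- vapply(events, function(e)
      e$kind == "gradient" && !(e$axis %in% ensemble$axes), logical(1))
    if (any(bad)) stop("gradient axis not available in ensemble config")
  }
  if (is.null(phase_cycle)) phase_cycle <- exorcycle(1)
  n_steps <- length(phase_cycle$receiver)
  if (!is.null(seed)) set.seed(seed)

  rho0 <- if (is.null(init)) equilibrium_state(sys)
          else if (is.function(init)) init(sys) else init
  dsys <- set_heteronuclear_decoupling(sys, TRUE)
  homo_views <- new.env(parent = emptyenv())

  chunks_sum <- NULL
  chunk_meta <- NULL
  final_states <- NULL

  for (step in seq_len(n_steps)) {
    rhos <- rep(list(rho0), nsl)
    wm <- water
    chunks <- list()
    for (ev in events) {
      if (ev$kind == "delay") {
        rhos <- lapply(rhos, propagate_cached, sys = sys,
                       duration = ev$duration, relax = relax)
        if (!is.null(wm)) wm <- evolve_water(wm, ev$duration)
      } else if (ev$kind == "hard_pulse") {
        ph <- resolve_phase(ev, phase_cycle, step)
        U <- hard_pulse_propagator(sys, ev$isotope, ev$flip, ph, ev$spins)
        Uh <- Conj(t(U))
        rhos <- lapply(rhos, function(r) U %*% r %*% Uh)
        if (!is.null(wm) && ev$isotope == "H1" && is.null(ev$spins))
          wm <- water_hard_pulse(wm, ev$flip, ph)
      } else if (ev$kind == "shaped_pulse") {
        ph <- resolve_phase(ev, phase_cycle, step)
        U <- shaped_pulse_propagator(sys, ev$shape, ev$duration, ev$peak_b1,
                                     ev$offset, ph, ev$isotope)
        Uh <- Conj(t(U))
        rhos <- lapply(rhos, function(r) {
          r <- U %*% r %*% Uh
          if (relax) apply_relaxation(r, sys, ev$duration) else r
        })
        if (!is.null(wm) && ev$isotope == "H1")
          wm <- water_shaped_pulse(wm, ev$shape, ev$duration, ev$peak_b1,
                                   ev$offset, ph)
      } else if (ev$kind == "gradient") {
        rhos <- lapply(rhos, propagate_cached, sys = sys,
                       duration = ev$duration, relax = relax)
        if (!is.null(wm)) wm <- evolve_water(wm, ev$duration)
        if (ev$amplitude != 0) {
          rhos <- apply_gradient(rhos, sys, z, ev$amplitude, ev$duration)
          if (!is.null(wm))
            wm <- water_gradient(wm, ev$amplitude, ev$duration)
        }
      } else if (ev$kind == "purge") {
        rhos <- lapply(rhos, function(r) {
          d <- diag(r); r[] <- 0i; diag(r) <- d; r
        })
        if (!is.null(wm)) { wm$M[1, ] <- 0; wm$M[2, ] <- 0 }
      } else if (ev$kind == "acquire") {
        asys <- if (ev$decouple) dsys else sys
        if (isTRUE(ev$homo_decouple)) {
          key <- if (ev$decouple) "hd1" else "hd0"
          if (is.null(homo_views[[key]]))
            homo_views[[key]] <- set_homonuclear_decoupling(asys, TRUE)
          asys <- homo_views[[key]]
        }
        D <- detection_operator(asys, ev$channel)
        tD <- t(D)
        U <- propagator_from_eigen(ham_eigen(asys), ev$dwell)
        Uh <- Conj(t(U))
        s <- complex(ev$n_points)
        for (k in seq_len(ev$n_points)) {
          sig <- mean(vapply(rhos, function(r) sum(r * tD), complex(1)))
          if (!is.null(wm)) sig <- sig + water_signal(wm)
          s[k] <- sig
          rhos <- lapply(rhos, function(r) {
            r <- U %*% r %*% Uh
            if (relax) apply_relaxation(r, asys, ev$dwell) else r
          })
          if (!is.null(wm)) wm <- evolve_water(wm, ev$dwell)
        }
        if (noise_sigma > 0)
          s <- s + complex(real = stats::rnorm(ev$n_points, 0, noise_sigma),
                           imaginary = stats::rnorm(ev$n_points, 0, noise_sigma))
        chunks[[length(chunks) + 1L]] <- s
        chunk_meta <- list(dwell = ev$dwell, n_points = ev$n_points)
      } else stop("unknown event kind: ", ev$kind)
    }
    rec <- exp(-1i * phase_cycle$receiver[step] * pi / 180)
    if (is.null(chunks_sum)) {
      chunks_sum <- lapply(chunks, function(sv) sv * rec)
    } else {
      if (length(chunks) != length(chunks_sum))
        stop("phase steps produced differing chunk counts")
      chunks_sum <- Map(function(a, b) a + b * rec, chunks_sum, chunks)
    }
    final_states <- rhos
  }
  chunks_sum <- lapply(chunks_sum, function(sv) sv / n_steps)

  out <- chunked_fid(chunks_sum,
                     dwell = chunk_meta$dwell %||% NA_real_,
                     sys = sys, seed = seed)
  if (return_state) return(list(fid = out, states = final_states))
  out
}

#' Chunked FID container
#'
#' @param chunks List of complex sample vectors (one per chunk).
#' @param dwell Dwell time (s).
#' @param sys Optional [spin_system()] supplying axis calibration.
#' @param seed Seed used for noise injection, if any.
#' @return A `chunked_fid` object.  `sw_ps`, the chunk repetition rate, is
#'   `1/(chunk_points * dwell)` when all chunks have equal length.
#' @export
chunked_fid <- function(chunks, dwell, sys = NULL, seed = NULL) {
  lens <- lengths(chunks)
  equal <- length(unique(lens)) <= 1
  structure(list(
    chunks = chunks, dwell = dwell,
    chunk_points = if (equal && length(lens)) lens[1] else NA_integer_,
    sw_ps = if (equal && length(lens)) 1 / (lens[1] * dwell) else NA_real_,
    carrier_ppm = if (!is.null(sys)) unname(sys$carrier_ppm["H1"]) else NA_real_,
    base_freq = if (!is.null(sys)) unname(sys$base_freq["H1"]) else NA_real_,
    seed = seed), class = "chunked_fid")
}

#' @export
print.chunked_fid <- function(x, ...) {
  cat(sprintf("<chunked_fid> %d chunk(s) x %s points, dwell %g us, sw_ps %s Hz\n",
              length(x$chunks), x$chunk_points, x$dwell * 1e6,
              format(x$sw_ps, digits = 4)))
  invisible(x)
}
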