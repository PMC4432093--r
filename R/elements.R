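# J-refocusing elements and real-time acquisition plans.
#
# Every element is a double spin echo.  The first echo is a hard 1H 180
# (with a 15N 180 alongside it for BIRD); the second is the discriminating
# echo: the BIRD sandwich 90x - 1/(2J) - 180x(1H)+180(15N) - 1/(2J) - 90x,
# or a band-selective reBURP 180 for BASHD.  With perfect pulses the net
# propagator is the identity on active (N-bound, in-band) protons -- no
# net shift evolution -- and a 180 on passive protons.  Overhead delays
# (blanking, power switching, the 15N-pulse time correction) are split
# symmetrically across the echo halves so the contract stays exact for
# instantaneous pulses.
#
# The two-step element phase cycle is a rigid 90 degree shift of all the
# element's 1H pulses: the wanted double-refocused pathway is invariant
# while single-refocusing error pathways invert and cancel.

#' Specify a J-refocusing element
#'
#' @param kind `"bird"`, `"bashd"`, `"gbird"`, `"gbashd"` (the `g` variants
#'   add coherence-transfer-pathway gradient pairs), or `"ideal"` (the
#'   zero-duration perfect-refocusing limit).
#' @param J_NH Nominal one-bond amide coupling (Hz).  The BIRD half-delay
#'   is `1/(2 J_NH)`, giving the field-independent core duration `1/J_NH`
#'   (11.1 ms at 90 Hz).
#' @param shape [pulse_shape()] for the band-selective 180 (BASHD kinds);
#'   defaults to [reburp_shape()].
#' @param shape_duration Band-selective pulse length (s).  The default
#'   2.44 ms reBURP gives about a 2 kHz refocusing band at 500 MHz.
#' @param shape_bandwidth Nominal bandwidth (Hz), recorded for reporting.
#' @param band_center_ppm Centre of the refocused (amide) band; the
#'   selective pulse is offset there as a phase-coherent phase ramp.
#' @param ctp_g1,ctp_g2 CTP gradient amplitudes (G/cm) for the two echoes.
#' @param ctp_duration Gradient pulse length (s).
#' @param ctp_axis Gradient axis.
#' @param delta1 Amplifier/receiver blanking delay (s).
#' @param delta2 Power-level switching delay (s).
#' @param delta3 Time correction associated with the second 15N 180 (s).
#' @param stabilization Gradient stabilization delay (s).
#' @param exorcycle_steps Element phase-cycle steps (1, 2 or 4).
#' @return An `element_spec` object.
#' @export
element_spec <- function(kind = c("bird", "bashd", "gbird", "gbashd", "ideal"),
                         J_NH = 90,
                         shape = NULL, shape_duration = 2.44e-3,
                         shape_bandwidth = 2000, band_center_ppm = 8.25,
                         ctp_g1 = 16.6, ctp_g2 = 13.6,
                         ctp_duration = 5e-4, ctp_axis = "z",
                         delta1 = 20e-6, delta2 = 50e-6, delta3 = 208e-6,
                         stabilization = 200e-6, exorcycle_steps = 2) {
  kind <- match.arg(kind)
  if (J_NH <= 0) stop("J_NH must be > 0")
  if (kind %in% c("bashd", "gbashd") && is.null(shape))
    shape <- reburp_shape()
  structure(list(kind = kind, J_NH = J_NH, shape = shape,
                 shape_duration = shape_duration,
                 shape_bandwidth = shape_bandwidth,
                 band_center_ppm = band_center_ppm,
                 ctp_g1 = ctp_g1, ctp_g2 = ctp_g2,
                 ctp_duration = ctp_duration, ctp_axis = ctp_axis,
                 delta1 = delta1, delta2 = delta2, delta3 = delta3,
                 stabilization = stabilization,
                 exorcycle_steps = exorcycle_steps),
            class = "element_spec")
}

#' @export
print.element_spec <- function(x, ...) {
  cat(sprintf("<element_spec> %s, J_NH %g Hz%s\n", x$kind, x$J_NH,
              if (x$kind %in% c("bashd", "gbashd"))
                sprintf(", %s %.3g ms", x$shape$name, x$shape_duration * 1e3)
              else ""))
  invisible(x)
}

PS_TABLE <- "ps_element"

el_pulse <- function(isotope, flip, phase, spins = NULL) {
  tab <- if (isotope == "H1") PS_TABLE else NULL
  ev_pulse(isotope, flip, phase, phase_table = tab, spins = spins)
}

#' Build a BIRD J-refocusing element
#'
#' Emits the double echo `[tau - 180y(1H) - tau]` followed by the BIRD
#' core `90x - Delta - 180x(1H) + 180(15N) - Delta - 90x` and a trailing
#' 15N 180 that restores the 15N z state, with `Delta = 1/(2 J_NH)`.  At
#' `J = J_NH` the net propagator (perfect pulses)
#' is the identity on N-bound protons with zero net shift evolution, and a
#' 180 rotation on remote protons.  For the `gbird` kind, CTP gradient
#' pairs are absorbed into the echo halves so every echo stays balanced.
#'
#' @param spec An [element_spec()] of kind `"bird"` or `"gbird"`.
#' @return Event list with attributes `duration` (exact sum of event
#'   durations) and `core_duration` (`1/J_NH`).
#' @export
bird_element <- function(spec) {
  stopifnot(inherits(spec, "element_spec"), spec$kind %in% c("bird", "gbird"))
  ctp <- spec$kind == "gbird"
  g_over <- if (ctp) spec$ctp_duration + spec$stabilization else 0
  delta <- 1 / (2 * spec$J_NH)
  if (delta <= g_over)
    stop("BIRD half-delay 1/(2 J_NH) too short to absorb the CTP gradient")
  tauA <- spec$delta1 + spec$delta2 / 2 + spec$delta3 / 2 + g_over

  half_A <- function(first) {
    evs <- list(ev_delay(tauA - g_over))
    if (ctp) {
      gr <- list(ev_gradient(spec$ctp_g1, spec$ctp_duration, spec$ctp_axis),
                 ev_delay(spec$stabilization))
      evs <- if (first) c(evs, gr) else c(gr[1], gr[2], evs)
    }
    evs
  }
  half_core <- function(first) {
    evs <- list(ev_delay(delta - g_over))
    if (ctp) {
      gr <- list(ev_gradient(spec$ctp_g2, spec$ctp_duration, spec$ctp_axis),
                 ev_delay(spec$stabilization))
      evs <- if (first) c(evs, gr) else c(gr[1], gr[2], evs)
    }
    evs
  }

  # The second 15N 180 trails the element (delta3, split symmetrically into
  # the echo halves, accounts for its timing): J_NH is then refocused in
  # echo A (1H-only 180) and the 15N z state is restored every element.
  events <- c(
    half_A(TRUE),
    list(el_pulse("H1", 180, 90)),
    half_A(FALSE),
    list(el_pulse("H1", 90, 0)),
    half_core(TRUE),
    list(el_pulse("H1", 180, 0), el_pulse("N15", 180, 0)),
    half_core(FALSE),
    list(el_pulse("H1", 90, 0), el_pulse("N15", 180, 0))
  )
  structure(events, duration = sequence_duration(events),
            core_duration = 2 * delta, kind = spec$kind)
}

#' Build a BASHD J-refocusing element
#'
#' Emits `[tau - 180x(1H) - tau]` followed by a symmetric echo around a
#' band-selective 180 (reBURP by default) centred on the amide band.  The
#' net propagator is the identity (no net shift evolution) for in-band
#' protons and a 180 rotation for out-of-band protons.  Both 180s share
#' the same base phase so their z-rotations cancel for in-band spins.
#'
#' @param spec An [element_spec()] of kind `"bashd"` or `"gbashd"`.
#' @param sys The [spin_system()] (supplies the carrier so the band centre
#'   offset can be computed).
#' @param peak_b1 Peak B1 of the selective pulse (Hz); calibrated with
#'   [calibrate_b1()] when `NULL`.
#' @return Event list with attributes `duration` and `core_duration` (the
#'   selective pulse length).
#' @export
bashd_element <- function(spec, sys, peak_b1 = NULL) {
  stopifnot(inherits(spec, "element_spec"),
            spec$kind %in% c("bashd", "gbashd"))
  if (is.null(spec$shape)) stop("BASHD element requires a pulse shape")
  ctp <- spec$kind == "gbashd"
  g_over <- if (ctp) spec$ctp_duration + spec$stabilization else 0
  if (is.null(peak_b1)) peak_b1 <- calibrate_b1(spec$shape, spec$shape_duration)
  offset <- ppm_to_offset_hz(spec$band_center_ppm,
                             sys$carrier_ppm[["H1"]],
                             sys$base_freq[["H1"]])
  tauA <- spec$delta1 + spec$delta2 / 2 + g_over
  tauB <- spec$delta3 / 2 + g_over

  wrap <- function(tau, g, core_evs) {
    pre <- list(ev_delay(tau - g_over))
    post <- list(ev_delay(tau - g_over))
    if (ctp) {
      pre <- c(pre, list(ev_gradient(g, spec$ctp_duration, spec$ctp_axis),
                         ev_delay(spec$stabilization)))
      post <- c(list(ev_gradient(g, spec$ctp_duration, spec$ctp_axis),
                     ev_delay(spec$stabilization)), post)
    }
    c(pre, core_evs, post)
  }

  events <- c(
    wrap(tauA, spec$ctp_g1, list(el_pulse("H1", 180, 0))),
    wrap(tauB, spec$ctp_g2,
         list(ev_shaped_pulse("H1", spec$shape, spec$shape_duration,
                              peak_b1, offset = offset, phase = 0,
                              phase_table = PS_TABLE)))
  )
  structure(events, duration = sequence_duration(events),
            core_duration = spec$shape_duration, kind = spec$kind)
}

# Zero-duration perfect-refocusing limit: instantaneous inversion of the
# passive 1H spins; chunks acquired with this element additionally run with
# active-passive homonuclear couplings suppressed (the limit the element
# train approaches as its duration and spacing go to zero).
ideal_element <- function(spec, sys) {
  pas <- sys$spins$label[sys$spins$role != "active" &
                           sys$spins$isotope == "H1"]
  events <- if (length(pas)) list(ev_pulse("H1", 180, 0, spins = pas))
            else list()
  structure(events, duration = 0, core_duration = 0, kind = "ideal")
}

#' Build the event list of a J-refocusing element
#'
#' Dispatches on the element kind; see [bird_element()], [bashd_element()].
#'
#' @inheritParams bashd_element
#' @param spec An [element_spec()].
#' @return Event list with a `duration` attribute.
#' @export
build_element <- function(spec, sys, peak_b1 = NULL) {
  switch(spec$kind,
         bird = , gbird = bird_element(spec),
         bashd = , gbashd = bashd_element(spec, sys, peak_b1),
         ideal = ideal_element(spec, sys))
}

#' Wrap refocusing blocks of an element with CTP gradient pairs
#'
#' Inserts a matched gradient (plus stabilization delay) on both sides of
#' each refocusing block of an existing element, absorbing the gradient
#' time into the neighbouring delays so echo symmetry and J-evolution
#' timing are preserved.  Blocks are the maximal runs of 180-degree pulses
#' (hard or shaped) on the observed channel; the first block takes `g1`,
#' all later ones `g2`.
#'
#' @param events Element event list (from [bird_element()] or
#'   [bashd_element()] without gradients).
#' @param g1,g2 Gradient amplitudes (G/cm).
#' @param duration Gradient length (s).
#' @param axis Gradient axis.
#' @param stabilization Stabilization delay after each gradient (s).
#' @return The wrapped event list (attributes preserved; total duration
#'   unchanged).
#' @export
ctp_wrap <- function(events, g1 = 16.6, g2 = 13.6, duration = 5e-4,
                     axis = "z", stabilization = 200e-6) {
  is180 <- vapply(events, function(e)
    (e$kind == "hard_pulse" && abs(e$flip) == 180 && e$isotope == "H1") ||
      e$kind == "shaped_pulse", logical(1))
  if (!any(is180)) stop("no refocusing block found to wrap")
  # maximal runs of refocusing pulses (1H 180s possibly interleaved with
  # 15N 180s count as one block)
  isblock <- vapply(events, function(e)
    e$kind %in% c("hard_pulse", "shaped_pulse") &&
      (e$kind == "shaped_pulse" || abs(e$flip) == 180), logical(1))
  runs <- rle(isblock)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # only runs containing an observed-channel refocusing pulse are wrapped
  run_has_h <- vapply(seq_along(runs$values), function(r)
    runs$values[r] && any(is180[starts[r]:ends[r]]), logical(1))
  over <- duration + stabilization
  out <- list()
  i <- 1
  bnum <- 0
  while (i <= length(events)) {
    r <- findInterval(i, starts)
    if (run_has_h[r] && i == starts[r]) {
      bnum <- bnum + 1
      g <- if (bnum == 1) g1 else g2
      # shrink preceding delay
      np <- length(out)
      if (np == 0 || out[[np]]$kind != "delay" ||
          out[[np]]$duration < over)
        stop("unbalanced CTP pair: adjacent delay shorter than gradient + stabilization (extend the echo half or use an explicit override)")
      out[[np]] <- ev_delay(out[[np]]$duration - over)
      out <- c(out, list(ev_gradient(g, duration, axis),
                         ev_delay(stabilization)))
      out <- c(out, events[starts[r]:ends[r]])
      i <- ends[r] + 1
      if (i > length(events) || events[[i]]$kind != "delay" ||
          events[[i]]$duration < over)
        stop("unbalanced CTP pair: adjacent delay shorter than gradient + stabilization (extend the echo half or use an explicit override)")
      out <- c(out, list(ev_gradient(g, duration, axis),
                         ev_delay(stabilization),
                         ev_delay(events[[i]]$duration - over)))
      i <- i + 1
    } else {
      out <- c(out, events[i])
      i <- i + 1
    }
  }
  attributes(out) <- attributes(events)[setdiff(names(attributes(events)),
                                                "names")]
  structure(out, duration = sequence_duration(out))
}

#' Plan a chunked real-time acquisition
#'
#' @param sw Direct-dimension spectral width (Hz); the dwell is `1/sw`.
#' @param total_points Total complex points across all chunks.
#' @param n_chunks Number of chunks; `total_points` must be divisible by
#'   `n_chunks` because the chunk rate `sw_ps` must be an integer
#'   submultiple of `sw`.
#' @param element An [element_spec()], or `NULL` for plain acquisition.
#' @param droppoints Leading points to drop from each chunk at processing.
#' @return An `acquisition_plan` with `chunk_points`, `chunk_duration` and
#'   `sw_ps` filled in.
#' @export
acquisition_plan <- function(sw, total_points, n_chunks = 1,
                             element = NULL, droppoints = 0) {
  stopifnot(sw > 0, total_points >= 1, n_chunks >= 1)
  if (total_points %% n_chunks != 0)
    stop("total_points must be divisible by n_chunks: sw_ps must be an integer submultiple of sw")
  chunk_points <- total_points / n_chunks
  if (droppoints >= chunk_points) stop("droppoints must be < chunk_points")
  structure(list(sw = sw, total_points = total_points, n_chunks = n_chunks,
                 chunk_points = chunk_points, dwell = 1 / sw,
                 chunk_duration = chunk_points / sw,
                 sw_ps = sw / chunk_points,
                 element = element, droppoints = droppoints),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> %d x %d points, sw %g Hz, chunk %.4g ms, sw_ps %.4g Hz, element %s\n",
              x$n_chunks, x$chunk_points, x$sw, x$chunk_duration * 1e3,
              x$sw_ps, if (is.null(x$element)) "none" else x$element$kind))
  invisible(x)
}

#' Real-time pure shift acquisition events
#'
#' Interleaves acquisition windows with J-refocusing elements so that the
#' J refocusing points fall at the centre of every chunk period: the first
#' and last windows are half a chunk long and the `n_chunks` elements sit
#' between them (`chunk/2 (element chunk) x (n-1) element chunk/2`).  The
#' homonuclear J phase then sweeps symmetrically about zero within each
#' chunk period and the decoupling sidebands appear at multiples of
#' `sw_ps = 1/(chunk duration)`.  With one chunk this reduces to plain
#' acquisition.
#'
#' @param plan An [acquisition_plan()].
#' @param sys The [spin_system()].
#' @param decouple Ideal heteronuclear decoupling during chunks.
#' @param peak_b1 Optional selective-pulse B1 override (BASHD).
#' @return Event list; combine with [exorcycle()] in [run_sequence()].
#' @export
realtime_acquisition <- function(plan, sys, decouple = TRUE,
                                 peak_b1 = NULL) {
  has_el <- !is.null(plan$element) && plan$n_chunks > 1
  homo <- !is.null(plan$element) && plan$element$kind == "ideal"
  if (!has_el) {
    events <- list(ev_acquire(plan$total_points, plan$dwell,
                              decouple = decouple, homo_decouple = homo))
    return(structure(events, duration = sequence_duration(events),
                     sw_ps = plan$sw_ps, element_duration = 0))
  }
  if (plan$chunk_points %% 2 != 0)
    stop("chunk_points must be even for the half-edge window layout")
  el <- build_element(plan$element, sys, peak_b1)
  half <- ev_acquire(plan$chunk_points / 2, plan$dwell, decouple = decouple,
                     homo_decouple = homo)
  full <- ev_acquire(plan$chunk_points, plan$dwell, decouple = decouple,
                     homo_decouple = homo)
  events <- list(half)
  for (k in seq_len(plan$n_chunks - 1)) events <- c(events, el, list(full))
  events <- c(events, el, list(half))
  structure(events, duration = sequence_duration(events),
            sw_ps = plan$sw_ps,
            element_duration = attr(el, "duration"))
}

#' Net propagator of an event list (no relaxation, single slice)
#'
#' Composes delay, pulse and gradient events at the coil centre into one
#' unitary; used for element-contract verification.
#'
#' @param sys A [spin_system()].
#' @param events Event list (no acquire events).
#' @param phase_cycle,step Optional phase-cycle context for tabled phases.
#' @return Complex unitary matrix.
#' @export
element_propagator <- function(sys, events, phase_cycle = NULL, step = 1L) {
  if (is.null(phase_cycle)) phase_cycle <- exorcycle(1)
  U <- diag(2^n_spins(sys))
  for (ev in events) {
    Uev <- switch(ev$kind,
      delay = ,
      gradient = propagator_from_eigen(ham_eigen(sys), ev$duration),
      hard_pulse = hard_pulse_propagator(sys, ev$isotope, ev$flip,
                                         resolve_phase(ev, phase_cycle, step),
                                         ev$spins),
      shaped_pulse = shaped_pulse_propagator(sys, ev$shape, ev$duration,
                                             ev$peak_b1, ev$offset,
                                             resolve_phase(ev, phase_cycle, step),
                                             ev$isotope),
      purge = stop("purge has no unitary representation"),
      stop("unsupported event kind: ", ev$kind))
    U <- Uev %*% U
  }
  U
}

#' Element contract fidelities
#'
#' Quantifies how well an element realises "identity on active protons,
#' inversion on passive protons": for each active 1H spin the average
#' survival of its `Ix` and `Iy` coherences (1 means shift-neutral
#' identity), and for each passive 1H spin the inversion efficiency of its
#' `Iz`.
#'
#' @param sys A [spin_system()].
#' @param events Element event list.
#' @return List with per-spin vectors `active_keep` and
#'   `passive_inversion`, and scalars `active_min`, `passive_min`.
#' @export
element_fidelity <- function(sys, events) {
  U <- element_propagator(sys, events)
  Uh <- Conj(t(U))
  keep <- function(A, B) {
    Re(sum(diag((U %*% A %*% Uh) %*% B))) / Re(sum(diag(B %*% B)))
  }
  act <- which(sys$spins$role == "active")
  pas <- which(sys$spins$role != "active" & sys$spins$isotope == "H1")
  ak <- vapply(act, function(i) {
    l <- sys$spins$label[i]
    (keep(single_spin_operator(sys, l, "x"), single_spin_operator(sys, l, "x")) +
     keep(single_spin_operator(sys, l, "y"), single_spin_operator(sys, l, "y"))) / 2
  }, numeric(1))
  pv <- vapply(pas, function(i) {
    l <- sys$spins$label[i]
    -keep(single_spin_operator(sys, l, "z"), single_spin_operator(sys, l, "z"))
  }, numeric(1))
  list(active_keep = stats::setNames(ak, sys$spins$label[act]),
       passive_inversion = stats::setNames(pv, sys$spins$label[pas]),
       active_min = if (length(ak)) min(ak) else NA_real_,
       passive_min = if (length(pv)) min(pv) else NA_real_)
}
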