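# Classical water magnetization.  Water is one-way coupled: it is co-evolved
# with the sequence and added to the receiver, but never enters the quantum
# density matrix.  Radiation damping uses the ensemble-mean transverse
# magnetization as the feedback field, so a gradient-dephased ensemble stops
# damping; for a spatially uniform ensemble this reduces to the per-slice
# form dMz/dt = +|Mt|^2/(tau_rd M0), dMt/dt = -Mz Mt/(tau_rd M0).
#
# Gradients wind phase both across slices (slice-centre phases) and within
# each slice; the intra-slice winding is tracked per slice as a linear
# phase density kappa (rad/cm) and enters detection and the damping field
# as the exact segment average sinc(kappa * width / 2).  A 180 pulse
# conjugates the transverse magnetization and flips kappa; other pulses
# collapse the intra-slice coherence before mixing.

#' Classical water magnetization model
#'
#' @param offset_hz Water resonance offset from the 1H carrier (Hz).
#' @param M0 Equilibrium magnitude in receiver units (much larger than the
#'   unit-amplitude solute signal).
#' @param T1,T2 Water relaxation times (s).
#' @param tau_rd Radiation damping time constant (s); `Inf` disables the
#'   feedback and leaves plain Bloch relaxation.
#' @param n_slices Number of spatial slices for the classical water grid.
#' @param length Sample extent (cm).
#' @param receiver_scale Scaling of the mean transverse water magnetization
#'   added to the receiver.
#' @return A `water_model` object carrying per-slice magnetization vectors.
#' @export
water_model <- function(offset_hz = 0, M0 = 50, T1 = 3, T2 = 0.5,
                        tau_rd = 5e-3, n_slices = 128, length = 1.6,
                        receiver_scale = 1) {
  stopifnot(tau_rd > 0, M0 >= 0, T1 > 0, T2 > 0, n_slices >= 1)
  z <- if (n_slices == 1) 0 else
    length * ((seq_len(n_slices) - 0.5) / n_slices - 0.5)
  M <- rbind(Mx = rep(0, n_slices), My = rep(0, n_slices),
             Mz = rep(M0, n_slices))
  structure(list(offset_hz = offset_hz, M0 = M0, T1 = T1, T2 = T2,
                 tau_rd = tau_rd, z = z, M = M,
                 kappa = rep(0, n_slices),
                 slice_width = length / n_slices,
                 receiver_scale = receiver_scale),
            class = "water_model")
}

#' @export
print.water_model <- function(x, ...) {
  cat(sprintf("<water_model> offset %g Hz, M0 %g, T1 %g s, T2 %g s, tau_rd %g s, %d slices\n",
              x$offset_hz, x$M0, x$T1, x$T2, x$tau_rd, length(x$z)))
  invisible(x)
}

# Intra-slice coherence factor sinc(kappa * w / 2) per slice.
slice_coherence <- function(wm) {
  a <- wm$kappa * wm$slice_width / 2
  ifelse(abs(a) < 1e-12, 1, sin(a) / a)
}

water_derivs <- function(M, wm, coh) {
  w <- 2 * pi * wm$offset_hz
  dM <- matrix(0, 3, ncol(M))
  dM[1, ] <- -w * M[2, ] - M[1, ] / wm$T2
  dM[2, ] <- w * M[1, ] - M[2, ] / wm$T2
  dM[3, ] <- (wm$M0 - M[3, ]) / wm$T1
  if (is.finite(wm$tau_rd) && wm$M0 > 0) {
    k <- 1 / (wm$tau_rd * wm$M0)
    bx <- mean(M[1, ] * coh); by <- mean(M[2, ] * coh)
    dM[1, ] <- dM[1, ] - k * M[3, ] * bx
    dM[2, ] <- dM[2, ] - k * M[3, ] * by
    dM[3, ] <- dM[3, ] + k * (M[1, ] * bx + M[2, ] * by)
  }
  dM
}

#' Evolve the water magnetization
#'
#' Fixed-step fourth-order Runge-Kutta integration (step at most 10 us) of
#' the Bloch equations with mean-field radiation damping.
#'
#' @param wm A [water_model()].
#' @param duration Evolution time (s).
#' @param max_step Maximum integrator step (s).
#' @return The evolved `water_model`.
#' @export
evolve_water <- function(wm, duration, max_step = 1e-5) {
  if (duration <= 0) return(wm)
  nst <- max(1L, ceiling(duration / max_step))
  h <- duration / nst
  M <- wm$M
  coh <- slice_coherence(wm)
  for (s in seq_len(nst)) {
    k1 <- water_derivs(M, wm, coh)
    k2 <- water_derivs(M + h / 2 * k1, wm, coh)
    k3 <- water_derivs(M + h / 2 * k2, wm, coh)
    k4 <- water_derivs(M + h * k3, wm, coh)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (any(!is.finite(M))) stop("water integration produced non-finite values")
  wm$M <- M
  wm
}

#' Manipulate the classical water magnetization
#'
#' `water_hard_pulse` rotates every slice by `flip` degrees about the
#' transverse axis at `phase` degrees; a 180 flips the intra-slice
#' winding, any other flip collapses it into an amplitude factor first.
#' `water_gradient` applies the per-slice gradient phase
#' `gamma_H * amplitude * z * duration` plus the intra-slice winding.
#' `water_shaped_pulse` applies the net rotation of a shaped pulse
#' evaluated at the water offset.  `water_signal` returns the complex
#' receiver contribution (slice mean weighted by the intra-slice
#' coherence factor).
#'
#' @param wm A [water_model()].
#' @param flip,phase Rotation angle and phase (degrees).
#' @return The updated `water_model` (`water_signal`: a complex scalar).
#' @export
water_hard_pulse <- function(wm, flip, phase = 0) {
  th <- flip * pi / 180; ph <- phase * pi / 180
  if (abs(abs(flip %% 360) - 180) < 1e-6) {
    wm$kappa <- -wm$kappa
  } else if (any(wm$kappa != 0)) {
    coh <- slice_coherence(wm)
    wm$M[1, ] <- wm$M[1, ] * coh
    wm$M[2, ] <- wm$M[2, ] * coh
    wm$kappa <- rep(0, length(wm$kappa))
  }
  n <- c(cos(ph), sin(ph), 0)
  wm$M <- rotate_vectors(wm$M, n, th)
  wm
}

#' @rdname water_hard_pulse
#' @param shape,duration,peak_b1,offset Shaped-pulse parameters as in
#'   [ev_shaped_pulse()]; relaxation during the pulse is neglected for the
#'   water vector.
#' @export
water_shaped_pulse <- function(wm, shape, duration, peak_b1, offset = 0,
                               phase = 0) {
  amps <- shape$samples$amplitude
  phs <- shape$samples$phase
  ns <- length(amps)
  dt <- duration / ns
  tmid <- (seq_len(ns) - 0.5) * dt
  dw <- 2 * pi * wm$offset_hz
  R <- diag(3)
  rot3 <- function(n, th) {
    c1 <- cos(th); s1 <- sin(th)
    K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
    c1 * diag(3) + s1 * K + (1 - c1) * outer(n, n)
  }
  for (k in seq_len(ns)) {
    phk <- (phase + phs[k]) * pi / 180 + 2 * pi * offset * (tmid[k] - duration / 2)
    wx <- 2 * pi * peak_b1 * amps[k] * cos(phk)
    wy <- 2 * pi * peak_b1 * amps[k] * sin(phk)
    w <- sqrt(wx^2 + wy^2 + dw^2)
    if (w == 0) next
    R <- rot3(c(wx, wy, dw) / w, w * dt) %*% R
  }
  # remove the pure precession the free evolution would have produced
  Rfree <- rot3(c(0, 0, 1), dw * duration)
  tilt <- max(abs(R - Rfree))
  if (tilt > 1e-3 && any(wm$kappa != 0)) {
    coh <- slice_coherence(wm)
    wm$M[1, ] <- wm$M[1, ] * coh
    wm$M[2, ] <- wm$M[2, ] * coh
    wm$kappa <- rep(0, length(wm$kappa))
  }
  wm$M <- R %*% wm$M
  wm
}

# Rodrigues rotation of 3 x n vectors about unit axis n by angle th
# (right-handed about the field, matching exp(-i th I_n) for spins).
rotate_vectors <- function(M, n, th) {
  c1 <- cos(th); s1 <- sin(th)
  dot <- n[1] * M[1, ] + n[2] * M[2, ] + n[3] * M[3, ]
  cr <- rbind(n[2] * M[3, ] - n[3] * M[2, ],
              n[3] * M[1, ] - n[1] * M[3, ],
              n[1] * M[2, ] - n[2] * M[1, ])
  M * c1 + cr * s1 + outer(n, dot) * (1 - c1)
}

#' @rdname water_hard_pulse
#' @param amplitude Gradient amplitude (G/cm).
#' @export
water_gradient <- function(wm, amplitude, duration) {
  phi <- GAMMA[["H1"]] * amplitude * wm$z * duration
  c1 <- cos(phi); s1 <- sin(phi)
  Mx <- wm$M[1, ] * c1 + wm$M[2, ] * s1
  My <- -wm$M[1, ] * s1 + wm$M[2, ] * c1
  wm$M[1, ] <- Mx; wm$M[2, ] <- My
  wm$kappa <- wm$kappa + GAMMA[["H1"]] * amplitude * duration
  wm
}

#' @rdname water_hard_pulse
#' @export
water_signal <- function(wm) {
  coh <- slice_coherence(wm)
  wm$receiver_scale * complex(real = mean(wm$M[1, ] * coh),
                              imaginary = mean(wm$M[2, ] * coh))
}
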