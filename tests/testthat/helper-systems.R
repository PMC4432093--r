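# Shared builders for the test suite.  Systems are rebuilt per file; the
# operator caches live on the objects, so reuse within a file is cheap.

# Two uncoupled-or-coupled protons at given offsets (Hz) relative to the
# carrier, no nitrogen.
two_proton_system <- function(dv1, dv2, J = 0, T2 = Inf, base_freq = 500) {
  spins <- rbind(
    spin("Ha", "H1", 4.7 + dv1 / base_freq, T2 = T2, role = "passive"),
    spin("Hb", "H1", 4.7 + dv2 / base_freq, T2 = T2, role = "passive"))
  Jm <- matrix(c(0, J, J, 0), 2, 2)
  spin_system(spins, Jm, base_freq = c(H1 = base_freq, N15 = 50.68))
}

# Plain acquisition of <I+> starting from total Ix, returning a spectrum.
simulate_1d <- function(sys, n_points = 512, dwell = 2e-4, zf = 8192,
                        decouple = FALSE, init = NULL, coupling_mode = NULL) {
  if (is.null(init)) {
    n <- n_spins(sys)
    init <- diag(2^n) / 2^n
    for (lab in sys$spins$label[sys$spins$isotope == "H1"])
      init <- init + single_spin_operator(sys, lab, "x")
  }
  cf <- run_sequence(sys, list(ev_acquire(n_points, dwell,
                                          decouple = decouple)),
                     init = init)
  zero_fill_and_ft(concatenate_chunks(cf), zf)
}

# Strongest real-part peak position of a spectrum (interpolated).
top_peak <- function(spec, mode = "real") {
  y <- if (mode == "real") Re(spec$intensity) else Mod(spec$intensity)
  pk <- peak_pick(spec, 0.5 * max(y), mode = mode)
  pk[which.max(pk$height), ]
}

# Real-time pure shift spectrum of an amide system with a given element.
pure_shift_spectrum <- function(sys, kind, total_points = 960, n_chunks = 6,
                                sw = 5000, zf = 16384, steps = 2,
                                relax = TRUE, n_slices = 8) {
  acq <- acquisition_plan(sw, total_points, n_chunks,
                          element = if (is.null(kind)) NULL
                                    else element_spec(kind))
  cf <- run_sequence(sys, realtime_acquisition(acq, sys),
                     ensemble = ensemble_config(n_slices),
                     phase_cycle = exorcycle(steps),
                     init = ideal_start_state(sys, 0, "cos"),
                     relax = relax)
  list(spec = zero_fill_and_ft(concatenate_chunks(cf), zf), acq = acq,
       cfid = cf)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
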