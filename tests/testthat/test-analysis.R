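test_that("peak picking interpolates singlets and resolves doublets", {
  # noiseless singlet slightly off the digital grid
  tt <- (0:4095) * 2e-4
  fd <- fid(exp(2i * pi * 301.3 * tt - tt / 0.1), 2e-4)
  sp <- zero_fill_and_ft(fd, 8192)
  pk <- peak_pick(sp, 0.5 * max(Re(sp$intensity)))
  expect_equal(nrow(pk), 1)
  digital <- 5000 / 8192
  expect_lt(abs(pk$freq_hz - 301.3), 0.5 * digital)
  # resolved doublet: separation within 2 %
  fdd <- fid(cos(pi * 40 * tt) * exp(2i * pi * 300 * tt - tt / 0.1), 2e-4)
  spd <- zero_fill_and_ft(fdd, 8192)
  pkd <- peak_pick(spd, 0.5 * max(Re(spd$intensity)))
  expect_equal(nrow(pkd), 2)
  expect_close(diff(pkd$freq_hz), 40, 0.8)
  expect_error(peak_pick(spectrum_1d(complex(2), 100), 1), "short")
})

test_that("overlapping amide doublets resolve only after homodecoupling", {
  residues <- generate_fixture("denatured_npgk", n_residues = 5, seed = 7)
  spec_of <- function(kind) {
    fids <- lapply(residues, function(sys) {
      acq <- acquisition_plan(5000, 960, if (is.null(kind)) 1 else 6,
                              element = if (is.null(kind)) NULL
                                        else element_spec(kind))
      concatenate_chunks(run_sequence(sys, realtime_acquisition(acq, sys),
                                      init = ideal_start_state(sys, 0, "cos")))
    })
    zero_fill_and_ft(apodize(combine_fids(fids), "gaussian", gf1 = 0.1),
                     16384)
  }
  sp_dec <- spec_of("ideal")
  pk_dec <- peak_pick(sp_dec, 0.25 * max(Re(sp_dec$intensity)),
                      min_separation = 2)
  expect_equal(nrow(pk_dec), 5)      # every residue resolved
  sp_cpl <- spec_of(NULL)
  pk_cpl <- peak_pick(sp_cpl, 0.25 * max(Re(sp_cpl$intensity)),
                      min_separation = 2)
  expect_false(nrow(pk_cpl) == 5)    # multiplet structure confuses picking
})

test_that("the S/N estimator is calibrated, linear and unbiased", {
  mk_spec <- function(A, sigma, seed) {
    set.seed(seed)
    intens <- complex(real = rnorm(4096, 0, sigma),
                      imaginary = rnorm(4096, 0, sigma))
    intens[2048] <- A   # noiseless peak point: exact linearity below
    spectrum_1d(intens, sw = 5000)
  }
  peak_reg <- c(-10, 10); noise_reg <- c(500, 2400)
  s1 <- snr(mk_spec(100, 2, 3), peak_reg, noise_reg)
  expect_close(s1, 50, 5)            # A/sigma within 10 %
  s2 <- snr(mk_spec(200, 2, 3), peak_reg, noise_reg)
  expect_equal(s2 / s1, 2, tolerance = 1e-10)  # same seed: exact linearity
  # unbiased within 2 standard errors over 32 seeds
  vals <- vapply(1:32, function(k) snr(mk_spec(100, 2, k), peak_reg,
                                       noise_reg), numeric(1))
  se <- stats::sd(vals) / sqrt(32)
  expect_lt(abs(mean(vals) - 50), 2 * se + 1.5)
  expect_error(snr(mk_spec(1, 1, 1), c(-10, 10), c(5, 100)), "disjoint")
})

test_that("sideband scanning reads positions at multiples of sw_ps", {
  sysr <- minimal_pair(J_HH = 8, T2 = 0.060)
  # ideal element with no homonuclear coupling: nothing to refocus, so the
  # run is identical to plain acquisition and the difference spectrum shows
  # no sidebands at all (the parent's own lineshape tails are subtracted)
  sys0 <- minimal_pair(J_HH = 0, T2 = 0.060)
  ps0 <- pure_shift_spectrum(sys0, "ideal", total_points = 960, n_chunks = 6)
  ref0 <- pure_shift_spectrum(sys0, NULL, total_points = 960, n_chunks = 1)
  dspec <- ps0$spec
  dspec$intensity <- ps0$spec$intensity - ref0$spec$intensity
  parent <- max(Mod(ps0$spec$intensity))
  f <- dspec$freq_hz
  at <- function(hz) Mod(dspec$intensity[which.min(abs(f - hz))])
  sb0 <- sapply(c(-2, -1, 1, 2), function(k) at(1770 + k * ps0$acq$sw_ps))
  expect_lt(max(sb0) / parent, 1e-6)
  # BIRD on a coupled pair: detectable first sidebands at +/- sw_ps
  ps2 <- pure_shift_spectrum(sysr, "bird", total_points = 1024, n_chunks = 2,
                             zf = 32768)
  sb2 <- sideband_scan(ps2$spec, 1770, ps2$acq$sw_ps, 1)
  expect_gt(max(sb2$lower[1], sb2$upper[1]), 0.05)
  # the scan errors outside the spectrum
  expect_error(sideband_scan(ps2$spec, 1770, 4000, 2), "outside")
})

test_that("multiplet collapse gains follow the intensity arithmetic", {
  expect_equal(max_multiplet_gain(c(1, 1)), 100)
  expect_equal(max_multiplet_gain(c(1, 2, 1)), 100)
  expect_equal(max_multiplet_gain(c(1, 3, 3, 1)), 100 * (8 / 3 - 1))
  expect_error(max_multiplet_gain(numeric(0)))
  expect_error(max_multiplet_gain(c(1, -1)))
})

test_that("doublet decoupling gain matches its closed form when unresolved", {
  expect_equal(decoupling_gain(0, 0.1), 0)
  expect_close(decoupling_gain(1000, 1), 100, 0.1)  # resolved limit
  # J T2 = 0.1: the gain has effectively vanished
  g <- decoupling_gain(2, 0.05)
  expect_close(g, 100 * (pi * 0.1 / 2)^2, 0.05)
  # closed form vs numeric maximization within 0.1 % up to J T2 = 0.15
  for (jt in c(0.02, 0.05, 0.1, 0.15)) {
    expect_close(decoupling_gain(jt / 0.06, 0.06),
                 decoupling_gain(jt / 0.06, 0.06, closed_form = TRUE), 0.1)
  }
  # element losses subtract from the singlet
  expect_lt(decoupling_gain(8, 0.06, element_loss = 0.3),
            decoupling_gain(8, 0.06))
})

test_that("time-shared sampling penalty is 1 - sqrt(duty)", {
  expect_close(duty_cycle_penalty(0.87), 6.73, 0.05)
  expect_equal(duty_cycle_penalty(1), 0)
  expect_equal(duty_cycle_penalty(0.25), 50)
  expect_error(duty_cycle_penalty(0))
})

test_that("water residual integrates the water window per spectrum", {
  sp0 <- spectrum_1d(complex(1024), sw = 5000)
  expect_equal(water_residual(sp0), 0)
  intens <- complex(1024); intens[513] <- 100  # on-carrier spike
  sp1 <- spectrum_1d(intens, sw = 5000)
  expect_gt(water_residual(sp1, 0, 50), 0)
  expect_equal(water_residual(sp1, 2000, 50), 0)
})

test_that("integral is conserved when a multiplet collapses (ideal element)", {
  sys <- minimal_pair(J_HH = 8, T2 = Inf)
  ps_c <- pure_shift_spectrum(sys, NULL, total_points = 960, n_chunks = 1,
                              relax = FALSE)
  ps_d <- pure_shift_spectrum(sys, "ideal", total_points = 960, n_chunks = 6,
                              relax = FALSE)
  int_c <- sum(Re(ps_c$spec$intensity))
  int_d <- sum(Re(ps_d$spec$intensity))
  expect_close(int_d / int_c, 1, 0.01)
})
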