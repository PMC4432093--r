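sys0 <- minimal_pair(J_HH = 0, T2 = Inf)      # clean contract checks
sysr <- minimal_pair(J_HH = 8, T2 = 0.060)    # realistic amide

test_that("the BIRD element realises its net-propagator contract", {
  spec <- element_spec("bird", J_NH = 90)
  el <- bird_element(spec)
  expect_equal(attr(el, "core_duration"), 1 / 90)   # 11.11 ms
  expect_equal(attr(el, "duration"), sequence_duration(el))
  f <- element_fidelity(sys0, el)
  expect_gte(f$active_min, 0.999)
  expect_gte(f$passive_min, 0.999)
  expect_error(element_spec("bird", J_NH = 0), "J_NH")
  # actual J different from nominal: residual errors grow
  sys80 <- amide_residue(J_NH = 80, J_HH = 0, T2 = Inf)
  f80 <- element_fidelity(sys80, el)
  expect_lt(f80$active_min, f$active_min)
  expect_gt(f$active_min - f80$active_min, 1e-3)
})

test_that("the BASHD element refocuses in-band and inverts out-of-band spins", {
  spec <- element_spec("bashd")
  el <- bashd_element(spec, sys0)
  expect_equal(attr(el, "core_duration"), 2.44e-3)
  f <- element_fidelity(sys0, el)
  expect_gte(f$active_min, 0.99)    # HN at 8.24 ppm, band centre 8.25
  expect_gte(f$passive_min, 0.99)   # HA at 4.3 ppm, far out of band
  expect_error(bashd_element(element_spec("bird"), sys0))
  # band-edge active spin: decoupling residual larger than at centre
  sys_edge <- amide_residue(h_ppm = 8.25 + 1000 / 500, J_HH = 0, T2 = Inf)
  f_edge <- element_fidelity(sys_edge, bashd_element(spec, sys_edge))
  expect_lt(f_edge$active_min, f$active_min)
})

test_that("a passive spin inside the selective band is recoupled", {
  # HA moved into the amide band: both spins refocused, J_HH survives
  sys_in <- amide_residue(ha_ppm = 7.9, J_HH = 8, T2 = 0.060)
  sys_out <- amide_residue(ha_ppm = 4.3, J_HH = 8, T2 = 0.060)
  h_in <- pure_shift_spectrum(sys_in, "bashd")$spec
  h_out <- pure_shift_spectrum(sys_out, "bashd")$spec
  # the decoupled singlet is taller than the recoupled (still split) peak
  expect_lt(max(Re(h_in$intensity)) / max(Re(h_out$intensity)), 0.8)
})

test_that("CTP wrapping preserves timing and the solute gradient echo", {
  specg <- element_spec("gbird")
  elg <- bird_element(specg)
  expect_equal(attr(elg, "core_duration"), 1 / 90)
  # gradients absorbed: same total duration as the plain element with the
  # same echo-half padding
  expect_equal(attr(elg, "duration"),
               attr(bird_element(element_spec("bird")), "duration") +
                 2 * (specg$ctp_duration + specg$stabilization))
  # solute signal with vs without CTP gradients (no relaxation)
  acq_b <- acquisition_plan(5000, 128, 2, element = element_spec("bird"))
  acq_g <- acquisition_plan(5000, 128, 2, element = specg)
  f_b <- concatenate_chunks(run_sequence(sys0, realtime_acquisition(acq_b, sys0),
                                         init = ideal_start_state(sys0, 0, "cos")))
  f_g <- concatenate_chunks(run_sequence(sys0, realtime_acquisition(acq_g, sys0),
                                         ensemble = ensemble_config(16),
                                         init = ideal_start_state(sys0, 0, "cos")))
  expect_gt(sum(Mod(f_g$samples)) / sum(Mod(f_b$samples)), 0.999)
  # explicit ctp_wrap of a padded element: balanced pairs, duration kept
  spec_pad <- element_spec("bird", delta1 = 8e-4)  # room for the gradients
  el_pad <- bird_element(spec_pad)
  wrapped <- ctp_wrap(el_pad, 16.6, 13.6, 5e-4, "z", 2e-4)
  expect_equal(sequence_duration(wrapped), sequence_duration(el_pad))
  expect_equal(sum(vapply(wrapped, function(e) e$kind == "gradient",
                          logical(1))), 4)
  f_w <- element_fidelity(sys0, wrapped)
  expect_gte(f_w$active_min, 0.999)
  # delays too short for the pair: explicit error
  expect_error(ctp_wrap(bird_element(element_spec("bird")), 16.6, 13.6,
                        5e-4, "z", 2e-4), "unbalanced")
})

test_that("real-time acquisition chunking follows the printed arithmetic", {
  p2 <- acquisition_plan(5000, 1024, 2, element = element_spec("bird"))
  expect_equal(p2$chunk_duration, 0.1024)
  expect_equal(p2$sw_ps, 5000 / 512)         # 9.77 Hz
  p8 <- acquisition_plan(5000, 1024, 8)
  expect_equal(p8$sw_ps, 39.0625)
  expect_error(acquisition_plan(5000, 1024, 3), "submultiple")
  expect_error(acquisition_plan(5000, 1024, 2, droppoints = 512), "droppoints")
  # one chunk reduces to plain acquisition
  p1 <- acquisition_plan(5000, 256, 1, element = element_spec("bird"))
  f1 <- concatenate_chunks(run_sequence(sysr, realtime_acquisition(p1, sysr),
                                        init = ideal_start_state(sysr, 0, "cos")))
  f0 <- concatenate_chunks(run_sequence(sysr, list(ev_acquire(256, 2e-4)),
                                        init = ideal_start_state(sysr, 0, "cos")))
  expect_lt(max(Mod(f1$samples - f0$samples)), 1e-12)
})

test_that("elements report durations exactly and BASHD is the shorter block", {
  for (kind in c("bird", "bashd", "gbird", "gbashd")) {
    spec <- element_spec(kind)
    el <- build_element(spec, sys0)
    expect_equal(attr(el, "duration"), sequence_duration(el))
  }
  d_bird <- attr(bird_element(element_spec("bird")), "duration")
  d_bashd <- attr(bashd_element(element_spec("bashd"), sys0), "duration")
  expect_lt(d_bashd, d_bird)
  expect_equal(attr(build_element(element_spec("ideal"), sys0), "duration"), 0)
})

test_that("pure shift singlets sit at the active-proton shift for both elements", {
  for (kind in c("bird", "bashd")) {
    ps <- pure_shift_spectrum(sysr, kind, zf = 32768)
    pk <- top_peak(ps$spec, "magnitude")
    digital <- 5000 / 32768
    expect_close(pk$freq_hz, 1770, max(digital, 0.2))
  }
})

test_that("decoupled linewidth grows with element duration under finite T2", {
  fw <- vapply(c("ideal", "bashd", "bird"), function(k)
    peak_fwhm(pure_shift_spectrum(sysr, k)$spec, 1770), numeric(1))
  expect_true(all(diff(fw) > 0))   # ideal < bashd < bird
  expect_gte(fw["ideal"], 1 / (pi * 0.060) - 1e-6)
})

test_that("2D HSQC places the cross peak at (nu_N, nu_H) in all modes", {
  expected_f1 <- ppm_to_offset_hz(114.15, 115, 50.68)
  hp <- hsqc_plan("ideal_start", n_t1 = 32, sw1 = 1500)
  acq <- acquisition_plan(5000, 256, 4, element = element_spec("ideal"))
  sp_i <- ft_2d(run_hsqc(sysr, hp, acq), zf2 = 2048, zf1 = 256,
                window_f1 = "gaussian", gf1 = 0.01)
  pk_i <- peak_position_2d(sp_i)
  expect_close(pk_i$f2_hz, 1770, 5000 / 2048)
  expect_close(pk_i$f1_hz, expected_f1, 1500 / 32)   # one pre-zero-fill point
  # explicit INEPT preparation: same peak position, proportional amplitude
  hp_e <- hsqc_plan("edited_gHSQC", n_t1 = 32, sw1 = 1500)
  sp_e <- ft_2d(run_hsqc(sysr, hp_e, acquisition_plan(5000, 256, 1)),
                zf2 = 2048, zf1 = 256, window_f1 = "gaussian", gf1 = 0.01)
  pk_e <- peak_position_2d(sp_e)
  sp_i1 <- ft_2d(run_hsqc(sysr, hp, acquisition_plan(5000, 256, 1)),
                 zf2 = 2048, zf1 = 256, window_f1 = "gaussian", gf1 = 0.01)
  pk_i1 <- peak_position_2d(sp_i1)
  expect_equal(pk_e$f1_hz, pk_i1$f1_hz)
  expect_equal(pk_e$f2_hz, pk_i1$f2_hz)
  ratio <- pk_e$height / pk_i1$height
  expect_gt(ratio, 0.1); expect_lt(ratio, 1.0)  # INEPT losses reported
  # sensitivity-enhanced echo/antiecho: pure-phase peak, no quad image
  hp_se <- hsqc_plan("gHSQC_SE", n_t1 = 32, sw1 = 1500)
  sp_se <- ft_2d(run_hsqc(sysr, hp_se, acquisition_plan(5000, 256, 1)),
                 zf2 = 2048, zf1 = 256, window_f1 = "gaussian", gf1 = 0.01)
  R <- Re(sp_se$intensity)
  pk <- which(R == max(R), arr.ind = TRUE)[1, ]
  i1m <- which.min(abs(sp_se$f1_hz + sp_se$f1_hz[pk[1]]))
  expect_lt(abs(R[i1m, pk[2]]) / R[pk[1], pk[2]], 0.01)
})

test_that("coupled doublet collapses to a singlet under gBIRD acquisition", {
  sys <- amide_residue(J_HH = 8, T2 = 0.2)
  acq_c <- acquisition_plan(5000, 1920, 1)
  f_c <- concatenate_chunks(run_sequence(sys, realtime_acquisition(acq_c, sys),
                                         init = ideal_start_state(sys, 0, "cos")))
  sp_c <- zero_fill_and_ft(f_c, 32768)
  pk_c <- peak_pick(sp_c, 0.5 * max(Re(sp_c$intensity)))
  expect_equal(nrow(pk_c), 2)      # J_HH doublet
  expect_close(diff(pk_c$freq_hz), 8, 0.5)
  ps <- pure_shift_spectrum(sys, "gbird", total_points = 1920, n_chunks = 8,
                            zf = 32768)
  pk_d <- peak_pick(ps$spec, 0.5 * max(Re(ps$spec$intensity)))
  expect_equal(nrow(pk_d), 1)      # collapsed singlet
})
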