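sys_hn <- minimal_pair(J_HH = 8, T2 = 0.060)

test_that("propagate handles edge cases and relaxation as documented", {
  H <- free_hamiltonian(sys_hn)
  rho0 <- ideal_start_state(sys_hn, 0, "cos")
  expect_identical(propagate(rho0, H, 0, sys_hn), rho0)
  # transverse coherence of an isolated spin decays as exp(-t/T2)
  sys1 <- spin_system(spin("a", "H1", 4.8, T2 = 0.05), strict = FALSE)
  rho <- diag(2) / 2 + single_spin_operator(sys1, "a", "x")
  r1 <- propagate(rho, free_hamiltonian(sys1), 0.03, sys1)
  mag <- function(r) {
    Ip <- single_spin_operator(sys1, "a", "+")
    Mod(sum(r * t(Ip)))
  }
  expect_equal(mag(r1) / mag(rho), exp(-0.03 / 0.05), tolerance = 1e-10)
  # semigroup without relaxation
  ra <- propagate(rho0, H, 0.013, sys_hn, relax = FALSE)
  rb <- propagate(propagate(rho0, H, 0.0065, sys_hn, relax = FALSE),
                  H, 0.0065, sys_hn, relax = FALSE)
  expect_lt(max(Mod(ra - rb)), 1e-10)
  # trace preserved with relaxation
  r2 <- propagate(equilibrium_state(sys_hn), H, 0.02, sys_hn)
  expect_equal(Re(sum(diag(r2))), 1, tolerance = 1e-10)
  expect_error(propagate(rho0, H + 0.1i * diag(nrow(H)), 1e-3), "Hermitian")
})

test_that("hard pulses follow the rotation conventions", {
  sys1 <- spin_system(spin("a", "H1", 4.7), strict = FALSE)
  rho <- equilibrium_state(sys1)
  r90 <- apply_hard_pulse(rho, sys1, "H1", 90, 0)
  Iy <- single_spin_operator(sys1, "a", "y")
  # 90x takes +z to -y
  expect_equal(Re(sum(r90 * t(Iy))) / Re(sum(Iy * t(Iy))), -1,
               tolerance = 1e-12)
  r360 <- apply_hard_pulse(apply_hard_pulse(rho, sys1, "H1", 180, 0),
                           sys1, "H1", 180, 0)
  expect_lt(max(Mod(r360 - rho)), 1e-12)
  # spin echo refocuses J_NH: 180 on H only at the echo midpoint
  rho0 <- ideal_start_state(sys_hn, 0, "cos")
  H <- free_hamiltonian(sys_hn)
  tau <- 3.3e-3
  r <- propagate(rho0, H, tau, sys_hn, relax = FALSE)
  r <- apply_hard_pulse(r, sys_hn, "H1", 180, 0)
  r <- propagate(r, H, tau, sys_hn, relax = FALSE)
  r <- apply_hard_pulse(r, sys_hn, "H1", 180, 0)  # undo inversion
  D <- single_spin_operator(sys_hn, "HN", "+")
  # J_NH and shift phases are refocused over the symmetric echo; the small
  # deficit is the (unrefocused) homonuclear J_HH evolution
  ov <- Mod(sum(r * t(D))) / Mod(sum(rho0 * t(D)))
  expect_gt(ov, abs(cos(pi * 8 * 2 * tau)) - 1e-3)
  expect_gt(ov, 0.95)
})

test_that("a rectangular shaped pulse reproduces a hard 180", {
  sys1 <- spin_system(spin("a", "H1", 4.7), strict = FALSE)
  rho <- equilibrium_state(sys1)
  Tp <- 1e-4
  rsh <- apply_shaped_pulse(rho, sys1, rect_shape(64), Tp, 1 / (2 * Tp),
                            relax = FALSE)
  rhd <- apply_hard_pulse(rho, sys1, "H1", 180, 0)
  expect_lt(max(Mod(rsh - rhd)), 1e-9)
  expect_error(ev_shaped_pulse("H1", rect_shape(64), 0, 100), "duration")
})

test_that("gradients dephase and balanced pairs refocus on every axis", {
  sys <- minimal_pair(J_HH = 0, T2 = Inf)
  init <- ideal_start_state(sys, 0, "cos")
  base <- run_sequence(sys, list(ev_delay(5e-4), ev_pulse("H1", 180, 0),
                                 ev_delay(5e-4), ev_acquire(2, 2e-4)),
                       init = init)
  for (ax in c("x", "y", "z")) {
    evg <- list(ev_gradient(16.6, 5e-4, ax), ev_pulse("H1", 180, 0),
                ev_gradient(16.6, 5e-4, ax), ev_acquire(2, 2e-4))
    cf <- run_sequence(sys, evg, ensemble = ensemble_config(64), init = init)
    expect_gt(Mod(cf$chunks[[1]][1]) / Mod(base$chunks[[1]][1]), 0.999)
  }
  # zero amplitude is a no-op
  rhos <- list(init, init)
  expect_identical(apply_gradient(rhos, sys, c(-0.4, 0.4), 0, 5e-4), rhos)
  # unavailable axis errors
  expect_error(run_sequence(sys, list(ev_gradient(10, 5e-4, "x"),
                                      ev_acquire(2, 2e-4)),
                            ensemble = ensemble_config(8, axes = "z"),
                            init = init),
               "axis")
})

test_that("acquire_chunk samples the analytic FID and seeds its noise", {
  sys1 <- spin_system(spin("a", "H1", 4.7 + 300 / 500, T2 = 0.05),
                      strict = FALSE)
  rho <- diag(2) / 2 + single_spin_operator(sys1, "a", "x")
  out <- acquire_chunk(rho, sys1, 256, 2e-4)
  tt <- (0:255) * 2e-4
  expect_lt(max(Mod(out$samples - exp(2i * pi * 300 * tt) * exp(-tt / 0.05))),
            1e-9)
  sp <- zero_fill_and_ft(fid(out$samples, 2e-4), 4096)
  expect_close(top_peak(sp, "magnitude")$freq_hz, 300, 5000 / 4096)
  # HN pair without decoupling: cos(pi J t) modulation
  sysp <- minimal_pair(J_HH = 0, T2 = Inf)
  rho2 <- ideal_start_state(sysp, 0, "cos")
  outc <- acquire_chunk(rho2, sysp, 64, 2e-4, decouple = FALSE)
  tt2 <- (0:63) * 2e-4
  model <- cos(pi * 90 * tt2) * exp(2i * pi * 1770 * tt2)
  expect_lt(max(Mod(outc$samples - model)), 1e-8)
  # seeded noise has the right mean behaviour
  means <- sapply(1:64, function(k)
    mean(Re(acquire_chunk(rho, sys1, 64, 2e-4, noise_sigma = 0.3,
                          seed = k)$samples)))
  clean <- mean(Re(acquire_chunk(rho, sys1, 64, 2e-4)$samples))
  se <- 0.3 / sqrt(64 * 64)
  expect_lt(abs(mean(means) - clean), 3 * se)
})

test_that("run_sequence composes, cycles phases and stays physical", {
  # empty plan: no chunks
  cf0 <- run_sequence(sys_hn, list())
  expect_length(cf0$chunks, 0)
  # one-spin pulse-acquire reproduces acquire_chunk exactly
  sys1 <- spin_system(spin("a", "H1", 4.9, T2 = 0.05), strict = FALSE)
  cf <- run_sequence(sys1, list(ev_pulse("H1", 90, 90),
                                ev_acquire(64, 2e-4)))
  rho <- apply_hard_pulse(equilibrium_state(sys1), sys1, "H1", 90, 90)
  ref <- acquire_chunk(rho, sys1, 64, 2e-4)
  expect_lt(max(Mod(cf$chunks[[1]] - ref$samples)), 1e-12)
  # 2-step element cycle equals 1-step when the element acts perfectly
  sysp2 <- minimal_pair(J_HH = 0, T2 = 0.060)
  acq <- acquisition_plan(5000, 128, 2, element = element_spec("bird"))
  ev <- realtime_acquisition(acq, sysp2)
  f1 <- concatenate_chunks(run_sequence(sysp2, ev, phase_cycle = exorcycle(1),
                                        init = ideal_start_state(sysp2, 0, "cos"),
                                        relax = FALSE))
  f2 <- concatenate_chunks(run_sequence(sysp2, ev, phase_cycle = exorcycle(2),
                                        init = ideal_start_state(sysp2, 0, "cos"),
                                        relax = FALSE))
  expect_lt(max(Mod(f1$samples - f2$samples)), 1e-8)
  # density matrix stays Hermitian with unit trace; purity behaves
  st <- run_sequence(sys_hn, ev, init = ideal_start_state(sys_hn, 0, "cos"),
                     return_state = TRUE)
  rhoF <- st$states[[1]]
  expect_lt(max(Mod(rhoF - Conj(t(rhoF)))), 1e-10)
  expect_equal(Re(sum(diag(rhoF))), 1, tolerance = 1e-10)
  pur0 <- Re(sum(diag(ideal_start_state(sys_hn, 0, "cos") %*%
                        ideal_start_state(sys_hn, 0, "cos"))))
  purF <- Re(sum(diag(rhoF %*% rhoF)))
  expect_lte(purF, pur0 + 1e-10)
  stNR <- run_sequence(sys_hn, ev, init = ideal_start_state(sys_hn, 0, "cos"),
                       relax = FALSE, return_state = TRUE)
  purNR <- Re(sum(diag(stNR$states[[1]] %*% stNR$states[[1]])))
  expect_equal(purNR, pur0, tolerance = 1e-10)
  # unresolved phase table reference errors
  expect_error(run_sequence(sys_hn, list(ev_pulse("H1", 90, 0,
                                                  phase_table = "nope")),
                            phase_cycle = exorcycle(2)),
               "unresolved")
})
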