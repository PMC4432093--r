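test_that("ppm to offset conversion follows the documented sign convention", {
  expect_equal(ppm_to_offset_hz(8.24, 4.7, 500), 1770)
  expect_equal(ppm_to_offset_hz(4.7, 4.7, 500), 0)
  expect_equal(ppm_to_offset_hz(114.15, 115, 50.68), -43.078, tolerance = 1e-9)
  expect_error(ppm_to_offset_hz(1, 0, -1))
})

test_that("spin system invariants are enforced", {
  expect_error(spin("W", "N15", 100, role = "water"), "water")
  expect_error(spin("H", "H1", 8, T2 = -1), "T2")
  # asymmetric J
  spins <- rbind(spin("a", "H1", 8), spin("b", "H1", 4))
  J <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(spin_system(spins, J), "symmetric")
  # active proton needs an amide-range 15N partner
  spins <- rbind(spin("HN", "H1", 8, role = "active"),
                 spin("N", "N15", 115))
  expect_error(spin_system(spins, matrix(c(0, 20, 20, 0), 2, 2)), "partner")
  expect_silent(spin_system(spins, matrix(c(0, 20, 20, 0), 2, 2),
                            strict = FALSE))
  # spin count cap
  spins7 <- do.call(rbind, lapply(1:7, function(i)
    spin(paste0("s", i), "H1", i)))
  expect_error(spin_system(spins7, matrix(0, 7, 7)), "6 spins")
})

test_that("single-spin operators obey the su(2) algebra on 1-4 spin systems", {
  for (n in 1:4) {
    spins <- do.call(rbind, lapply(seq_len(n), function(i)
      spin(paste0("s", i), if (i %% 2) "H1" else "N15", i)))
    sys <- spin_system(spins, matrix(0, n, n), strict = FALSE)
    for (i in seq_len(n)) {
      lab <- spins$label[i]
      Ix <- single_spin_operator(sys, lab, "x")
      Iy <- single_spin_operator(sys, lab, "y")
      Iz <- single_spin_operator(sys, lab, "z")
      expect_lt(max(Mod(Ix %*% Iy - Iy %*% Ix - 1i * Iz)), 1e-14)
      expect_lt(max(Mod(Iy %*% Iz - Iz %*% Iy - 1i * Ix)), 1e-14)
      expect_lt(max(Mod(Iz %*% Ix - Ix %*% Iz - 1i * Iy)), 1e-14)
    }
  }
  sys1 <- spin_system(spin("a", "H1", 8), strict = FALSE)
  expect_equal(single_spin_operator(sys1, "a", "z"),
               diag(c(0.5, -0.5)), ignore_attr = TRUE)
  # operators of different spins commute
  sys2 <- two_proton_system(100, -100)
  A <- single_spin_operator(sys2, "Ha", "x")
  B <- single_spin_operator(sys2, "Hb", "z")
  expect_lt(max(Mod(A %*% B - B %*% A)), 1e-14)
  expect_error(single_spin_operator(sys2, "nope", "x"), "unknown")
})

test_that("free Hamiltonians are Hermitian for randomized systems", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    spins <- do.call(rbind, lapply(seq_len(n), function(i)
      spin(paste0("s", i), sample(c("H1", "N15"), 1), runif(1, -5, 10))))
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- runif(sum(upper.tri(J)), -20, 20)
    J <- J + t(J)
    sys <- spin_system(spins, J, strict = FALSE)
    for (mode in c("full", "weak", "heteronuclear_secular")) {
      H <- free_hamiltonian(sys, mode)
      expect_lt(max(Mod(H - Conj(t(H)))), 1e-12 * max(1, max(Mod(H))))
    }
  }
})

test_that("one-spin Hamiltonian has eigenvalues +/- pi nu", {
  sys <- spin_system(spin("a", "H1", 4.7 + 100 / 500), strict = FALSE)
  ev <- sort(Re(eigen(free_hamiltonian(sys))$values))
  expect_equal(ev, c(-pi * 100, pi * 100), tolerance = 1e-10)
})

test_that("weak coupling gives a first-order doublet; equivalent spins collapse", {
  sys <- two_proton_system(400, -400, J = 20, T2 = 0.15)
  sp <- simulate_1d(sys, 1024)
  pk <- peak_pick(sp, 0.4 * max(Re(sp$intensity)))
  expect_equal(nrow(pk), 4)  # two doublets
  hi <- pk[pk$freq_hz > 0, ]
  expect_close(diff(hi$freq_hz), 20, 0.4)  # within 2 %
  # equivalent spins, full coupling: J invisible
  sys_eq <- two_proton_system(150, 150, J = 10, T2 = 0.15)
  sp_eq <- simulate_1d(sys_eq, 1024)
  pk_eq <- peak_pick(sp_eq, 0.4 * max(Re(sp_eq$intensity)))
  expect_equal(nrow(pk_eq), 1)
  expect_close(pk_eq$freq_hz, 150, 0.5)
})

test_that("weak and full modes agree in line positions when Dnu/J >= 100", {
  sysf <- two_proton_system(600, -600, J = 10)
  pos <- lapply(c("full", "weak"), function(m) {
    H <- free_hamiltonian(sysf, m)
    n <- n_spins(sysf)
    rho <- diag(2^n) / 2^n +
      (single_spin_operator(sysf, "Ha", "x") +
         single_spin_operator(sysf, "Hb", "x")) / 2^(n - 2)
    D <- single_spin_operator(sysf, "Ha", "+") +
      single_spin_operator(sysf, "Hb", "+")
    dwell <- 2e-4
    s <- complex(512)
    U <- NULL
    e <- eigen(H)
    U <- e$vectors %*% diag(exp(-1i * Re(e$values) * dwell)) %*% Conj(t(e$vectors))
    r <- rho
    for (k in 1:512) { s[k] <- sum(r * t(D)); r <- U %*% r %*% Conj(t(U)) }
    sp <- zero_fill_and_ft(fid(s, dwell), 16384)
    peak_pick(sp, 0.4 * max(Re(sp$intensity)))$freq_hz
  })
  expect_equal(length(pos[[1]]), length(pos[[2]]))
  expect_true(all(abs(pos[[1]] - pos[[2]]) <= 0.001 * abs(pos[[2]]) + 0.02))
})

test_that("heteronuclear decoupling view zeroes only H-N couplings", {
  sys <- minimal_pair(J_HH = 8)
  dsys <- set_heteronuclear_decoupling(sys, TRUE)
  expect_equal(dsys$J["HN", "N"], 0)
  expect_equal(dsys$J["HN", "HA"], 8)
  back <- set_heteronuclear_decoupling(dsys, FALSE)
  expect_equal(back$J["HN", "N"], 90)
  # spectra: doublet split by J_NH without decoupling, singlet with
  sys0 <- minimal_pair(J_HH = 0)
  spd <- simulate_1d(sys0, 1024, decouple = TRUE,
                     init = ideal_start_state(sys0, 0, "cos"))
  spc <- simulate_1d(sys0, 1024, decouple = FALSE,
                     init = ideal_start_state(sys0, 0, "cos"))
  pkd <- peak_pick(spd, 0.5 * max(Re(spd$intensity)))
  pkc <- peak_pick(spc, 0.3 * max(Re(spc$intensity)))
  expect_equal(nrow(pkd), 1)
  expect_equal(nrow(pkc), 2)
  expect_close(diff(pkc$freq_hz), 90, 1)
})

test_that("spin systems round-trip through the YAML schema", {
  sys <- minimal_pair(J_HH = 7.25, T2 = 0.055)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spin_system(sys, path)
  sys2 <- read_spin_system(path)
  expect_identical(sys2$spins$label, sys$spins$label)  # incl. the bare "N"
  expect_equal(sys2$spins$shift_ppm, sys$spins$shift_ppm)
  expect_equal(sys2$spins$T2, sys$spins$T2)
  expect_equal(sys2$J, sys$J, ignore_attr = TRUE)
  expect_equal(sys2$base_freq, sys$base_freq)
  # malformed file
  writeLines("spins: []", path)
  expect_error(read_spin_system(path), "base_freq")
})
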