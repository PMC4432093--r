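# Product-operator algebra on the 2^n tensor-product basis.  Spin order in
# the Kronecker products follows the row order of sys$spins; the first spin
# is the slowest-varying index.

PAULI <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = diag(c(0.5, -0.5)),
  `+` = matrix(c(0, 0, 1, 0), 2, 2),   # I+ = Ix + i Iy
  `-` = matrix(c(0, 1, 0, 0), 2, 2),
  e = diag(2)
)

#' Embed a single-spin operator in the full system space
#'
#' @param sys A [spin_system()].
#' @param label Spin label.
#' @param axis One of `"x"`, `"y"`, `"z"`, `"+"`, `"-"`.
#' @return A complex `2^n` by `2^n` matrix.
#' @export
single_spin_operator <- function(sys, label, axis = c("x", "y", "z", "+", "-")) {
  axis <- match.arg(axis)
  i <- spin_index(sys, label)
  key <- paste0("op_", i, "_", axis)
  cached <- sys$cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- n_spins(sys)
  mats <- rep(list(PAULI$e), n)
  mats[[i]] <- PAULI[[axis]]
  out <- Reduce(kronecker, mats)
  sys$cache[[key]] <- out
  out
}

# Sum of I_axis over a set of spin indices.
total_operator <- function(sys, idx, axis) {
  if (!length(idx)) return(matrix(0i, 2^n_spins(sys), 2^n_spins(sys)))
  Reduce(`+`, lapply(sys$spins$label[idx], single_spin_operator,
                     sys = sys, axis = axis))
}

isotope_indices <- function(sys, isotope) which(sys$spins$isotope == isotope)

#' Free-evolution Hamiltonian of a spin system
#'
#' Builds `H = sum_i 2 pi nu_i I_iz + sum_(i<j) 2 pi J_ij C_ij` in rad/s,
#' where the coupling term `C_ij` is the full isotropic product `Ii.Ij` or
#' the secular (weak-coupling) term `Iiz Ijz` depending on `coupling_mode`.
#' In the default `"heteronuclear_secular"` mode, same-isotope pairs use the
#' full isotropic coupling and heteronuclear pairs the secular term, which
#' is exact in the doubly rotating frame.
#'
#' @param sys A [spin_system()].
#' @param coupling_mode `"heteronuclear_secular"` (default), `"full"`, or
#'   `"weak"`.
#' @return A Hermitian complex matrix (rad/s).
#' @export
free_hamiltonian <- function(sys,
                             coupling_mode = c("heteronuclear_secular",
                                               "full", "weak")) {
  coupling_mode <- match.arg(coupling_mode)
  key <- paste0("ham_", coupling_mode)
  cached <- sys$cache[[key]]
  if (!is.null(cached)) return(cached)

  n <- n_spins(sys)
  off <- spin_offsets_hz(sys)
  H <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n))
    H <- H + 2 * pi * off[i] *
      single_spin_operator(sys, sys$spins$label[i], "z")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Jij <- sys$J[i, j]
    if (Jij == 0) next
    same <- sys$spins$isotope[i] == sys$spins$isotope[j]
    full <- switch(coupling_mode,
                   full = TRUE, weak = FALSE,
                   heteronuclear_secular = same)
    li <- sys$spins$label[i]; lj <- sys$spins$label[j]
    term <- single_spin_operator(sys, li, "z") %*%
      single_spin_operator(sys, lj, "z")
    if (full)
      term <- term +
        single_spin_operator(sys, li, "x") %*% single_spin_operator(sys, lj, "x") +
        single_spin_operator(sys, li, "y") %*% single_spin_operator(sys, lj, "y")
    H <- H + 2 * pi * Jij * term
  }
  sys$cache[[key]] <- H
  H
}

# Eigen-decomposition of a Hermitian matrix, cached per system + mode, so
# that propagators for arbitrary durations are a diagonal exponential away.
ham_eigen <- function(sys, coupling_mode = "heteronuclear_secular") {
  key <- paste0("eig_", coupling_mode)
  cached <- sys$cache[[key]]
  if (!is.null(cached)) return(cached)
  H <- free_hamiltonian(sys, coupling_mode)
  e <- eigen(H)
  e$values <- Re(e$values)
  sys$cache[[key]] <- e
  e
}

# exp(-i H t) for Hermitian H given its eigen-decomposition.
propagator_from_eigen <- function(e, t) {
  ph <- exp(-1i * e$values * t)
  e$vectors %*% (ph * Conj(t(e$vectors)))
}

# exp(-i G theta) for a Hermitian generator (used for pulses).
rotation_operator <- function(G, theta) {
  if (max(abs(G - Conj(t(G)))) > 1e-9 * max(1, max(abs(G))))
    stop("rotation generator must be Hermitian")
  e <- eigen(G)
  propagator_from_eigen(list(values = Re(e$values), vectors = e$vectors),
                        theta)
}

#' Thermal-equilibrium density matrix
#'
#' Identity/2^n plus z polarization on each spin proportional to its
#' gyromagnetic ratio (1H normalized to 1).
#'
#' @param sys A [spin_system()].
#' @return A density matrix with unit trace.
#' @export
equilibrium_state <- function(sys) {
  n <- n_spins(sys)
  rho <- diag(2^n) / 2^n
  pol <- c(H1 = 1, N15 = GAMMA_RATIO_N15)
  for (i in seq_len(n))
    rho <- rho + pol[[sys$spins$isotope[i]]] *
      single_spin_operator(sys, sys$spins$label[i], "z") / 2^(n - 1)
  rho
}

#' Detection operator
#'
#' `I+` summed over the non-water spins of one isotope, normalized so an
#' in-phase `Ix` coherence yields unit signal amplitude.
#'
#' @param sys A [spin_system()].
#' @param isotope Observed isotope.
#' @param exclude_roles Roles omitted from detection.
#' @return A complex matrix.
#' @export
detection_operator <- function(sys, isotope = "H1",
                               exclude_roles = "water") {
  idx <- which(sys$spins$isotope == isotope &
                 !(sys$spins$role %in% exclude_roles))
  total_operator(sys, idx, "+") / 2^(n_spins(sys) - 2)
}

# Per-pair transverse relaxation rate matrix: coherence rho[a, b] decays at
# the sum of 1/T2 over the spins whose basis state differs between a and b,
# so a single-quantum coherence of spin i decays at exactly 1/T2_i and
# multiple-quantum coherences at the sum over their flipped spins.
relaxation_rates <- function(sys) {
  cached <- sys$cache[["r2mat"]]
  if (!is.null(cached)) return(cached)
  n <- n_spins(sys)
  r2 <- ifelse(is.na(sys$spins$T2) | !is.finite(sys$spins$T2),
               0, 1 / sys$spins$T2)
  bits <- sapply(seq_len(n), function(i)
    bitwAnd(seq_len(2^n) - 1L, bitwShiftL(1L, n - i)) > 0)
  bits <- matrix(bits, ncol = n)
  R <- matrix(0, 2^n, 2^n)
  for (i in seq_len(n)) {
    diff_i <- outer(bits[, i], bits[, i], `!=`)
    R <- R + r2[i] * diff_i
  }
  r1 <- 1 / sys$spins$T1
  r1 <- r1[!is.na(r1) & is.finite(r1)]
  out <- list(R2 = R, r1bar = if (length(r1)) mean(r1) else 0)
  sys$cache[["r2mat"]] <- out
  out
}
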