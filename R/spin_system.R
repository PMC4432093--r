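#' @keywords internal
"_PACKAGE"

# Gyromagnetic ratios, rad s^-1 G^-1.  1H is the CODATA value; 15N is scaled
# by the gamma ratio -0.10137 (negative gyromagnetic ratio).
GAMMA_H1 <- 26752.218744
GAMMA_RATIO_N15 <- -0.10137
GAMMA <- c(H1 = GAMMA_H1, N15 = GAMMA_H1 * GAMMA_RATIO_N15)

ISOTOPES <- c("H1", "N15")
SPIN_ROLES <- c("active", "passive", "water")

#' Convert a chemical shift to a rotating-frame offset
#'
#' Offsets follow the convention that a resonance at higher ppm than the
#' carrier has a positive offset in Hz: `offset = (shift - carrier) * base_freq`.
#'
#' @param shift_ppm Chemical shift (ppm).
#' @param carrier_ppm Transmitter (carrier) position (ppm).
#' @param base_freq_mhz Larmor frequency of the isotope (MHz).
#' @return Offset from the carrier in Hz.
#' @examples
#' ppm_to_offset_hz(8.24, 4.7, 500) # 1770 Hz
#' @export
ppm_to_offset_hz <- function(shift_ppm, carrier_ppm, base_freq_mhz) {
  stopifnot(base_freq_mhz > 0)
  (shift_ppm - carrier_ppm) * base_freq_mhz
}

#' Define a nuclear spin
#'
#' @param label Unique spin label, e.g. `"HN"`.
#' @param isotope `"H1"` or `"N15"`.
#' @param shift_ppm Chemical shift (ppm).
#' @param T2 Transverse relaxation time (s); `Inf` disables T2 loss.
#' @param T1 Longitudinal relaxation time (s) or `NA` to freeze populations.
#' @param role `"active"` (observed, N-bound proton), `"passive"`, or
#'   `"water"` (only meaningful for 1H).
#' @return A one-row data frame describing the spin.
#' @export
spin <- function(label, isotope, shift_ppm, T2 = Inf, T1 = NA_real_,
                 role = "passive") {
  isotope <- match.arg(isotope, ISOTOPES)
  role <- match.arg(role, SPIN_ROLES)
  if (!is.na(T2) && T2 <= 0) stop("T2 must be > 0")
  if (!is.na(T1) && T1 <= 0) stop("T1 must be > 0")
  if (role == "water" && isotope != "H1") stop("role 'water' requires a 1H spin")
  data.frame(label = label, isotope = isotope, shift_ppm = shift_ppm,
             T2 = T2, T1 = T1, role = role, stringsAsFactors = FALSE)
}

#' Build a spin system
#'
#' A spin system bundles up to six spins, their scalar-coupling matrix, and
#' the spectrometer frame (Larmor frequencies and carrier positions per
#' isotope).  All simulation routines consume this object.
#'
#' @param spins A data frame of spins, usually `rbind()` of [spin()] rows.
#' @param J Symmetric scalar-coupling matrix in Hz (zero diagonal), with
#'   dimnames matching the spin labels, or `NULL` for an uncoupled system.
#' @param base_freq Named numeric: Larmor frequency per isotope in MHz.
#' @param carrier_ppm Named numeric: carrier position per isotope in ppm.
#' @param strict If `TRUE` (default), require every `active` 1H spin to have
#'   exactly one 15N partner with `|J|` between 80 and 105 Hz (the one-bond
#'   amide coupling range).  Set `FALSE` to override for non-amide studies.
#' @return An object of class `spin_system`.
#' @examples
#' sys <- minimal_pair()
#' sys
#' @export
spin_system <- function(spins, J = NULL,
                        base_freq = c(H1 = 500, N15 = 50.68),
                        carrier_ppm = c(H1 = 4.7, N15 = 115),
                        strict = TRUE) {
  stopifnot(is.data.frame(spins), nrow(spins) >= 1)
  n <- nrow(spins)
  if (n > 6) stop("spin systems are limited to 6 spins (matrix dimension 64)")
  if (anyDuplicated(spins$label)) stop("spin labels must be unique")
  if (is.null(J)) J <- matrix(0, n, n)
  J <- as.matrix(J)
  stopifnot(nrow(J) == n, ncol(J) == n)
  if (max(abs(J - t(J))) > 0) stop("J must be symmetric")
  if (any(diag(J) != 0)) stop("J must have a zero diagonal")
  dimnames(J) <- list(spins$label, spins$label)
  if (any(!is.na(spins$T2) & spins$T2 <= 0)) stop("T2 must be > 0")

  if (strict) {
    for (i in which(spins$role == "active")) {
      if (spins$isotope[i] != "H1")
        stop("role 'active' is reserved for 1H spins")
      partners <- which(spins$isotope == "N15" & abs(J[i, ]) >= 80 &
                          abs(J[i, ]) <= 105)
      if (length(partners) != 1)
        stop(sprintf(
          "active spin '%s' needs exactly one 15N partner with |J| in [80, 105] Hz (use strict = FALSE to override)",
          spins$label[i]))
    }
  }

  missing_iso <- setdiff(unique(spins$isotope), names(base_freq))
  if (length(missing_iso))
    stop("base_freq missing isotope(s): ", paste(missing_iso, collapse = ", "))

  sys <- list(spins = spins, J = J, base_freq = base_freq,
              carrier_ppm = carrier_ppm,
              hetero_decoupled = FALSE,
              cache = new.env(parent = emptyenv()))
  class(sys) <- "spin_system"
  sys
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d spins%s\n", nrow(x$spins),
              if (isTRUE(x$hetero_decoupled)) " (1H-15N decoupled view)" else ""))
  print(x$spins, row.names = FALSE)
  nz <- which(upper.tri(x$J) & x$J != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("couplings (Hz):\n")
    for (k in seq_len(nrow(nz)))
      cat(sprintf("  %s-%s: %g\n", rownames(x$J)[nz[k, 1]],
                  colnames(x$J)[nz[k, 2]], x$J[nz[k, 1], nz[k, 2]]))
  }
  invisible(x)
}

#' Number of spins in a system
#' @param sys A [spin_system()].
#' @return Integer spin count.
#' @export
n_spins <- function(sys) nrow(sys$spins)

spin_index <- function(sys, label) {
  i <- match(label, sys$spins$label)
  if (anyNA(i)) stop("unknown spin label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' Rotating-frame offsets of every spin
#'
#' @param sys A [spin_system()].
#' @return Named numeric vector of offsets (Hz) relative to each isotope's
#'   carrier.
#' @export
spin_offsets_hz <- function(sys) {
  off <- ppm_to_offset_hz(sys$spins$shift_ppm,
                          sys$carrier_ppm[sys$spins$isotope],
                          sys$base_freq[sys$spins$isotope])
  names(off) <- sys$spins$label
  off
}

#' Toggle ideal heteronuclear decoupling
#'
#' Returns a view of the system whose 1H-15N couplings are zeroed, modelling
#' ideal broadband 15N decoupling during acquisition windows.  Homonuclear
#' couplings are untouched.
#'
#' @param sys A [spin_system()].
#' @param on `TRUE` to zero the heteronuclear couplings.
#' @return A `spin_system` view.
#' @export
set_heteronuclear_decoupling <- function(sys, on = TRUE) {
  if (isTRUE(on) == isTRUE(sys$hetero_decoupled)) return(sys)
  out <- sys
  out$hetero_decoupled <- isTRUE(on)
  out$cache <- new.env(parent = emptyenv())
  if (isTRUE(on)) {
    iso <- sys$spins$isotope
    het <- outer(iso, iso, function(a, b) a != b)
    out$J[het] <- 0
    attr(out$J, "undecoupled") <- sys$J
  } else if (!is.null(attr(sys$J, "undecoupled"))) {
    out$J <- attr(sys$J, "undecoupled")
  }
  out
}

#' Toggle ideal homonuclear (pure shift) decoupling
#'
#' Returns a view with the active-passive homonuclear couplings zeroed:
#' the zero-duration, perfect-refocusing limit of a pure shift element
#' train (used by the `ideal` element kind).
#'
#' @param sys A [spin_system()].
#' @param on `TRUE` to zero active-passive 1H-1H couplings.
#' @return A `spin_system` view.
#' @export
set_homonuclear_decoupling <- function(sys, on = TRUE) {
  if (!isTRUE(on)) return(sys)
  out <- sys
  out$cache <- new.env(parent = emptyenv())
  act <- sys$spins$role == "active"
  pas <- sys$spins$role != "active" & sys$spins$isotope == "H1"
  mask <- outer(act, pas) | outer(pas, act)
  out$J[mask] <- 0
  out
}
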