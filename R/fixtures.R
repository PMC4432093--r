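# Synthetic amide spin systems emulating the benchmark samples: a
# denatured small-domain protein (narrow amide dispersion, T2 ~ 60 ms), a
# folded globular protein (T2 ~ 35 ms), and a small antifungal protein
# (T2 ~ 55 ms).  Each residue is an independent HN-N-Halpha three-spin
# system; inter-residue couplings are neglected.

FIXTURE_STYLES <- list(
  denatured_npgk = list(T2 = 0.060, h_range = c(7.8, 8.7),
                        n_range = c(105, 125), ha_range = c(3.9, 4.7)),
  ubiquitin_like = list(T2 = 0.035, h_range = c(7.0, 9.5),
                        n_range = c(105, 130), ha_range = c(3.7, 5.2)),
  paf_like = list(T2 = 0.055, h_range = c(7.2, 9.3),
                  n_range = c(105, 128), ha_range = c(3.8, 5.0))
)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic spin-system fixture
#'
#' @param style `"denatured_npgk"`, `"ubiquitin_like"`, `"paf_like"` or
#'   `"minimal_pair"`.
#' @param n_residues Number of amide residues.
#' @param seed RNG seed; the same seed always yields the identical system.
#' @param J_NH One-bond amide coupling (Hz).
#' @param J_HH_range Range of the vicinal HN-Halpha coupling (Hz), drawn
#'   uniformly per residue.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(style = c("denatured_npgk", "ubiquitin_like",
                                   "paf_like", "minimal_pair"),
                         n_residues = 5, seed = 1, J_NH = 90,
                         J_HH_range = c(4, 9)) {
  style <- match.arg(style)
  structure(list(style = style, n_residues = n_residues, seed = seed,
                 J_NH = J_NH, J_HH_range = J_HH_range),
            class = "fixture_spec")
}

#' Generate synthetic amide spin systems
#'
#' Deterministically builds HN-N-Halpha three-spin systems in the chosen
#' style: amide protons in the style's 1H range, 15N in 105-125 ppm-ish
#' ranges, one passive Halpha per residue with a vicinal coupling drawn
#' uniformly from `J_HH_range`, and the style's T2 on every proton.
#'
#' @param spec A [fixture_spec()], or a style name (extra arguments are
#'   forwarded to [fixture_spec()]).
#' @param ... Forwarded to [fixture_spec()] when `spec` is a style name.
#' @return For `"minimal_pair"`, a single [spin_system()]; otherwise a
#'   list of per-residue `spin_system`s.
#' @export
generate_fixture <- function(spec = "minimal_pair", ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$style == "minimal_pair") return(minimal_pair(J_NH = spec$J_NH))
  st <- FIXTURE_STYLES[[spec$style]]
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_residues), function(r) {
      hs <- stats::runif(1, st$h_range[1], st$h_range[2])
      ns <- stats::runif(1, st$n_range[1], st$n_range[2])
      ha <- stats::runif(1, st$ha_range[1], st$ha_range[2])
      jhh <- stats::runif(1, spec$J_HH_range[1], spec$J_HH_range[2])
      amide_residue(h_ppm = hs, n_ppm = ns, ha_ppm = ha,
                    J_NH = spec$J_NH, J_HH = jhh, T2 = st$T2)
    })
  })
}

#' Single amide residue spin system
#'
#' @param h_ppm,n_ppm,ha_ppm Chemical shifts of the amide proton, its 15N
#'   and the alpha proton.
#' @param J_NH One-bond coupling (Hz).
#' @param J_HH Vicinal HN-Halpha coupling (Hz).
#' @param T2 Proton transverse relaxation time (s); 15N T2 is set 3x
#'   longer.
#' @param T1 Optional longitudinal relaxation time (s).
#' @param base_freq,carrier_ppm Frame, as in [spin_system()].
#' @return A [spin_system()].
#' @export
amide_residue <- function(h_ppm = 8.24, n_ppm = 114.15, ha_ppm = 4.3,
                          J_NH = 90, J_HH = 6, T2 = 0.060, T1 = NA,
                          base_freq = c(H1 = 500, N15 = 50.68),
                          carrier_ppm = c(H1 = 4.7, N15 = 115)) {
  spins <- rbind(
    spin("HN", "H1", h_ppm, T2 = T2, T1 = T1, role = "active"),
    spin("N", "N15", n_ppm, T2 = 3 * T2, T1 = T1, role = "passive"),
    spin("HA", "H1", ha_ppm, T2 = T2, T1 = T1, role = "passive"))
  J <- matrix(0, 3, 3)
  J[1, 2] <- J[2, 1] <- J_NH
  J[1, 3] <- J[3, 1] <- J_HH
  spin_system(spins, J, base_freq = base_freq, carrier_ppm = carrier_ppm)
}

#' Minimal amide pair fixture
#'
#' The smallest interesting system: HN-N-Halpha with `J_NH = 90` Hz.
#'
#' @inheritParams amide_residue
#' @return A [spin_system()].
#' @export
minimal_pair <- function(J_NH = 90, J_HH = 6, T2 = 0.060) {
  amide_residue(J_NH = J_NH, J_HH = J_HH, T2 = T2)
}

#' Sum FIDs of independently simulated residues
#'
#' @param fids List of [fid()]s with identical dwell and calibration.
#' @return A single [fid()] with summed samples.
#' @export
combine_fids <- function(fids) {
  stopifnot(length(fids) >= 1)
  dw <- vapply(fids, function(f) f$dwell, numeric(1))
  if (length(unique(dw)) > 1) stop("FIDs differ in dwell")
  out <- fids[[1]]
  out$samples <- Reduce(`+`, lapply(fids, function(f) f$samples))
  out
}
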