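# 2D HSQC skeletons feeding the real-time pure shift acquisition.

#' Plan a 2D HSQC experiment
#'
#' @param variant `"ideal_start"` starts each t1 record directly from
#'   in-phase amide 1H coherence amplitude-modulated by the 15N shift
#'   (isolating the pure shift acquisition from INEPT details);
#'   `"edited_gHSQC"` runs an explicit INEPT - t1 - back-INEPT preparation;
#'   `"gHSQC_SE"` produces echo/antiecho record pairs for Rance-Kay
#'   processing.
#' @param n_t1 Number of t1 increments.
#' @param sw1 Indirect (15N) spectral width (Hz); the t1 dwell is `1/sw1`.
#' @param relaxation_delay Inter-scan delay (s); bookkeeping only, the
#'   simulation restarts each scan from its initial state.
#' @return An `hsqc_plan` object.
#' @export
hsqc_plan <- function(variant = c("ideal_start", "edited_gHSQC", "gHSQC_SE"),
                      n_t1 = 64, sw1 = 1500, relaxation_delay = 1) {
  variant <- match.arg(variant)
  stopifnot(n_t1 >= 1, sw1 > 0)
  structure(list(variant = variant, n_t1 = n_t1, sw1 = sw1,
                 dwell1 = 1 / sw1,
                 echo_antiecho = variant == "gHSQC_SE",
                 relaxation_delay = relaxation_delay),
            class = "hsqc_plan")
}

# Active 1H spins and their one-bond 15N partners.
active_pairs <- function(sys) {
  act <- which(sys$spins$role == "active")
  partners <- vapply(act, function(i) {
    p <- which(sys$spins$isotope == "N15" & abs(sys$J[i, ]) >= 80 &
                 abs(sys$J[i, ]) <= 105)
    if (length(p) != 1)
      stop("active spin without a unique 15N partner: ", sys$spins$label[i])
    p
  }, integer(1))
  data.frame(h = act, n = partners)
}

#' Idealized HSQC start state
#'
#' In-phase transverse coherence on every active proton, amplitude- (or
#' phase-) modulated by its 15N partner's offset at the given t1: the state
#' an ideal INEPT - t1 - back-INEPT preparation would deliver.  Components
#' `cos`/`sin` give States quadrature records, `echo`/`antiecho` the
#' gradient-selected pair.
#'
#' @param sys A [spin_system()].
#' @param t1 Indirect evolution time (s).
#' @param component Quadrature component.
#' @return A density matrix for the `init` argument of [run_sequence()].
#' @export
ideal_start_state <- function(sys, t1, component = c("cos", "sin",
                                                     "echo", "antiecho")) {
  component <- match.arg(component)
  pairs <- active_pairs(sys)
  off <- spin_offsets_hz(sys)
  n <- n_spins(sys)
  rho <- diag(2^n) / 2^n
  for (k in seq_len(nrow(pairs))) {
    lab <- sys$spins$label[pairs$h[k]]
    w <- 2 * pi * off[pairs$n[k]]
    Ix <- single_spin_operator(sys, lab, "x")
    Iy <- single_spin_operator(sys, lab, "y")
    # unscaled Ix: together with the detection normalization this gives
    # unit signal amplitude per active proton for any spin count
    rho <- rho + switch(component,
      cos = cos(w * t1) * Ix,
      sin = sin(w * t1) * Ix,
      echo = cos(w * t1) * Ix + sin(w * t1) * Iy,
      antiecho = cos(w * t1) * Ix - sin(w * t1) * Iy)
  }
  rho
}

# Explicit INEPT - t1 - back-INEPT preparation events.  `quad` selects the
# quadrature component via the phase of the 15N excitation pulse.
inept_events <- function(sys, t1, J_NH = 90, quad = c("cos", "sin")) {
  quad <- match.arg(quad)
  d <- 1 / (4 * J_NH)
  ph_n1 <- if (quad == "cos") 0 else 270
  c(list(
    ev_pulse("H1", 90, 0),
    ev_delay(d),
    ev_pulse("H1", 180, 0), ev_pulse("N15", 180, 0),
    ev_delay(d),
    ev_pulse("H1", 90, 90), ev_pulse("N15", 90, ph_n1),
    ev_delay(t1 / 2),
    ev_pulse("H1", 180, 0),
    ev_delay(t1 / 2),
    ev_pulse("N15", 90, 0), ev_pulse("H1", 90, 0),
    ev_delay(d),
    ev_pulse("H1", 180, 0), ev_pulse("N15", 180, 0),
    ev_delay(d)
  ))
}

#' Run a 2D (pure shift) HSQC simulation
#'
#' Simulates every t1 increment (and quadrature component) of an HSQC whose
#' direct dimension uses the chunked real-time acquisition of
#' `acquisition_plan`.  Chunks are concatenated per increment.
#'
#' @param sys A [spin_system()].
#' @param plan An [hsqc_plan()].
#' @param acq An [acquisition_plan()].
#' @param ensemble An [ensemble_config()].
#' @param water Optional [water_model()]; re-initialized each increment.
#' @param noise_sigma,seed Noise injection passed to [run_sequence()].
#' @param phase_cycle Optional phase cycle; defaults to the element's
#'   EXORCYCLE steps when the plan carries an element.
#' @return An `hsqc_data` object: a matrix-like list of direct-dimension
#'   [fid()]s per t1 increment with axis metadata for [ft_2d()].
#' @export
run_hsqc <- function(sys, plan, acq, ensemble = ensemble_config(),
                     water = NULL, noise_sigma = 0, seed = NULL,
                     phase_cycle = NULL) {
  events_acq <- realtime_acquisition(acq, sys)
  if (is.null(phase_cycle)) {
    steps <- if (!is.null(acq$element)) acq$element$exorcycle_steps else 1
    phase_cycle <- exorcycle(steps)
  }
  comps <- if (plan$echo_antiecho) c("echo", "antiecho") else c("cos", "sin")
  recs <- vector("list", plan$n_t1)
  for (it in seq_len(plan$n_t1)) {
    t1 <- (it - 1) * plan$dwell1
    rec <- lapply(comps, function(cp) {
      if (plan$variant == "edited_gHSQC") {
        prep <- inept_events(sys, t1,
                             J_NH = median(abs(sys$J)[abs(sys$J) >= 80 &
                                                        abs(sys$J) <= 105]),
                             quad = if (cp %in% c("cos", "echo")) "cos" else "sin")
        cf <- run_sequence(sys, c(prep, events_acq), ensemble = ensemble,
                           phase_cycle = phase_cycle, water = water,
                           noise_sigma = noise_sigma,
                           seed = if (is.null(seed)) NULL else seed + it)
      } else {
        cf <- run_sequence(sys, events_acq, ensemble = ensemble,
                           phase_cycle = phase_cycle, water = water,
                           init = ideal_start_state(sys, t1, cp),
                           noise_sigma = noise_sigma,
                           seed = if (is.null(seed)) NULL else seed + it)
      }
      concatenate_chunks(cf, droppoints = acq$droppoints)
    })
    names(rec) <- comps
    recs[[it]] <- rec
  }
  structure(list(records = recs, sw1 = plan$sw1, n_t1 = plan$n_t1,
                 echo_antiecho = plan$echo_antiecho,
                 carrier_ppm_f1 = unname(sys$carrier_ppm["N15"]),
                 base_freq_f1 = unname(sys$base_freq["N15"]),
                 variant = plan$variant),
            class = "hsqc_data")
}

#' @export
print.hsqc_data <- function(x, ...) {
  cat(sprintf("<hsqc_data> %s, %d t1 increments (%s), sw1 %g Hz\n",
              x$variant, x$n_t1,
              if (x$echo_antiecho) "echo/antiecho" else "States cos/sin",
              x$sw1))
  invisible(x)
}
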