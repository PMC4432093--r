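# Pulse-sequence events.  A sequence plan is an ordinary list of events;
# element builders return such lists with a "duration" attribute equal to
# the exact sum of their event durations.

new_event <- function(kind, ...) {
  ev <- list(kind = kind, ...)
  class(ev) <- "nmr_event"
  ev
}

#' Sequence events
#'
#' Constructors for the events understood by [run_sequence()]: free
#' evolution delays, instantaneous hard pulses, shaped (selective) pulses,
#' pulsed field gradients, windowed acquisition, and transverse purge.
#'
#' Hard and shaped pulses may carry a `phase_table` name; the actual pulse
#' phase is then `phase + table[step]` where the table is looked up in the
#' `phase_cycle` argument of [run_sequence()].
#'
#' @param duration Event duration (s).
#' @param isotope Channel, `"H1"` or `"N15"`.
#' @param flip Flip angle (degrees).
#' @param phase RF phase (degrees; 0 = x, 90 = y).
#' @param phase_table Optional name of a phase-cycle table.
#' @param shape A [pulse_shape()].
#' @param peak_b1 Peak RF amplitude (Hz).
#' @param offset Transmitter offset of the shaped pulse (Hz), implemented as
#'   a phase-coherent frequency-modulated phase ramp.
#' @param amplitude Gradient amplitude (G/cm).
#' @param axis Gradient axis (`"x"`, `"y"`, or `"z"`).
#' @param n_points Number of complex points in this acquisition chunk.
#' @param dwell Dwell time (s).
#' @param channel Observed isotope.
#' @param decouple Apply ideal heteronuclear decoupling during the chunk.
#' @param homo_decouple Additionally zero the active-passive homonuclear
#'   couplings during the chunk (the perfect-refocusing limit used by the
#'   `ideal` element).
#' @return An event object.
#' @name events
NULL

#' @rdname events
#' @export
ev_delay <- function(duration) {
  stopifnot(duration >= 0)
  new_event("delay", duration = duration)
}

#' @rdname events
#' @param spins Optional character vector of spin labels the pulse acts on
#'   (defaults to every spin of the isotope); used for idealized selective
#'   inversions.
#' @export
ev_pulse <- function(isotope = "H1", flip = 90, phase = 0, phase_table = NULL,
                     spins = NULL) {
  isotope <- match.arg(isotope, ISOTOPES)
  new_event("hard_pulse", isotope = isotope, flip = flip, phase = phase,
            phase_table = phase_table, spins = spins, duration = 0)
}

#' @rdname events
#' @export
ev_shaped_pulse <- function(isotope = "H1", shape, duration, peak_b1,
                            offset = 0, phase = 0, phase_table = NULL) {
  stopifnot(inherits(shape, "pulse_shape"))
  if (duration <= 0) stop("shaped pulse duration must be > 0")
  if (nrow(shape$samples) < 32) stop("shape must have at least 32 samples")
  new_event("shaped_pulse", isotope = match.arg(isotope, ISOTOPES),
            shape = shape, duration = duration, peak_b1 = peak_b1,
            offset = offset, phase = phase, phase_table = phase_table)
}

#' @rdname events
#' @export
ev_gradient <- function(amplitude, duration, axis = "z") {
  stopifnot(duration >= 0)
  new_event("gradient", amplitude = amplitude, duration = duration,
            axis = match.arg(axis, c("x", "y", "z")))
}

#' @rdname events
#' @export
ev_acquire <- function(n_points, dwell, channel = "H1", decouple = TRUE,
                       homo_decouple = FALSE) {
  stopifnot(n_points >= 1, dwell > 0)
  new_event("acquire", n_points = as.integer(n_points), dwell = dwell,
            channel = match.arg(channel, ISOTOPES), decouple = decouple,
            homo_decouple = homo_decouple,
            duration = n_points * dwell)
}

#' @rdname events
#' @export
ev_purge <- function() new_event("purge", duration = 0)

#' @export
print.nmr_event <- function(x, ...) {
  cat("<event>", x$kind,
      paste(sprintf("%s=%s",
                    setdiff(names(x), c("kind", "shape")),
                    sapply(x[setdiff(names(x), c("kind", "shape"))],
                           function(v) paste(format(v), collapse = ","))),
            collapse = " "), "\n")
  invisible(x)
}

#' Exact total duration of an event list
#'
#' @param events List of events.
#' @return Sum of the event durations (s).
#' @export
sequence_duration <- function(events) {
  sum(vapply(events, function(e) e$duration %||% 0, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial ensemble configuration for gradient simulations
#'
#' Positions are slice midpoints, symmetric about the coil centre.  A
#' single-slice ensemble (the default when no gradients are present)
#' reduces the engine to one density matrix at the coil centre.
#'
#' @param n_slices Number of spatial positions.
#' @param length Sample extent along the gradient axis (cm).
#' @param stabilization Gradient stabilization delay (s) used by element
#'   builders.
#' @param axes Gradient axes available on the (virtual) probe.
#' @return An `ensemble_config` object.
#' @export
ensemble_config <- function(n_slices = 64, length = 1.6,
                            stabilization = 200e-6,
                            axes = c("x", "y", "z")) {
  stopifnot(n_slices >= 1, length > 0)
  z <- if (n_slices == 1) 0 else
    length * ((seq_len(n_slices) - 0.5) / n_slices - 0.5)
  structure(list(n_slices = n_slices, length = length, z = z,
                 stabilization = stabilization, axes = axes,
                 gamma = GAMMA),
            class = "ensemble_config")
}

#' Two-step element phase cycle (EXORCYCLE-style)
#'
#' The retained pathway through a J-refocusing element passes through two
#' refocusing sandwiches, so a rigid 90 degree phase shift of all the
#' element's 1H pulses leaves the wanted signal invariant while inverting
#' single-refocusing error pathways; the receiver is held constant.
#'
#' @param steps 1, 2, or 4 steps.
#' @param table Name of the phase table attached to element pulses.
#' @return A phase-cycle list for [run_sequence()].
#' @export
exorcycle <- function(steps = 2, table = "ps_element") {
  stopifnot(steps %in% c(1, 2, 4))
  ph <- switch(as.character(steps),
               "1" = 0, "2" = c(0, 90), "4" = c(0, 90, 180, 270))
  pc <- list(tables = list(ph), receiver = rep(0, steps))
  names(pc$tables) <- table
  pc
}
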