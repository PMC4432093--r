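# Selective pulse envelopes and their characterization.

# Fourier-cosine coefficients of the reBURP refocusing envelope
# (Geen & Freeman, J. Magn. Reson. 93, 93-141, 1991; Table for RE-BURP).
# omega1(t)/omega_max = a0 + sum_n an cos(2 pi n t / Tp), t in [0, Tp].
REBURP_COEF <- c(0.49, -1.02, 1.11, -1.57, 0.83, -0.42, 0.26, -0.16,
                 0.10, -0.07, 0.04, -0.03, 0.01, -0.02, 0.00, -0.01)

#' Pulse shape container
#'
#' @param amplitude Relative amplitude samples; the maximum absolute value
#'   is normalized to 1.
#' @param phase Phase samples (degrees), recycled to the amplitude length.
#' @param name Shape name.
#' @return A `pulse_shape` object.
#' @export
pulse_shape <- function(amplitude, phase = 0, name = "custom") {
  stopifnot(length(amplitude) >= 32)
  m <- max(abs(amplitude))
  if (m == 0) stop("shape must have nonzero amplitude")
  structure(list(
    samples = data.frame(amplitude = amplitude / m,
                         phase = rep_len(phase, length(amplitude))),
    name = name), class = "pulse_shape")
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat(sprintf("<pulse_shape> '%s', %d samples, mean |a| %.3f\n",
              x$name, nrow(x$samples), mean(abs(x$samples$amplitude))))
  invisible(x)
}

#' reBURP band-selective refocusing envelope
#'
#' Pure amplitude modulation (constant phase) synthesized from the
#' published Fourier-cosine coefficient table; the envelope is symmetric
#' about its midpoint and has small negative lobes.
#'
#' @param n_samples Number of waveform samples (at least 64).
#' @return A [pulse_shape()].
#' @export
reburp_shape <- function(n_samples = 256) {
  stopifnot(n_samples >= 64)
  tt <- (seq_len(n_samples) - 0.5) / n_samples
  a <- as.numeric(outer(tt, seq_along(REBURP_COEF) - 1,
                        function(x, k) cos(2 * pi * k * x)) %*% REBURP_COEF)
  pulse_shape(a, 0, "reburp")
}

#' Rectangular (hard) envelope
#'
#' @param n_samples Number of samples.
#' @return A [pulse_shape()].
#' @export
rect_shape <- function(n_samples = 64) {
  pulse_shape(rep(1, n_samples), 0, "rect")
}

# Bloch integration of a shape on an isolated spin, vectorized over offsets.
# Returns the full magnetization matrix (3 x n_offsets) from initial +z.
bloch_profile <- function(shape, duration, peak_b1, offsets_hz) {
  amps <- shape$samples$amplitude
  phs <- shape$samples$phase
  ns <- length(amps)
  dt <- duration / ns
  no <- length(offsets_hz)
  Mx <- numeric(no); My <- numeric(no); Mz <- rep(1, no)
  wz <- 2 * pi * offsets_hz
  for (k in seq_len(ns)) {
    phk <- phs[k] * pi / 180
    wx <- 2 * pi * peak_b1 * amps[k] * cos(phk)
    wy <- 2 * pi * peak_b1 * amps[k] * sin(phk)
    w <- sqrt(wx^2 + wy^2 + wz^2)
    ang <- w * dt
    nx <- ifelse(w > 0, wx / w, 0)
    ny <- ifelse(w > 0, wy / w, 0)
    nz <- ifelse(w > 0, wz / w, 1)
    c1 <- cos(ang); s1 <- sin(ang)
    dot <- nx * Mx + ny * My + nz * Mz
    Mx2 <- Mx * c1 + (ny * Mz - nz * My) * s1 + nx * dot * (1 - c1)
    My2 <- My * c1 + (nz * Mx - nx * Mz) * s1 + ny * dot * (1 - c1)
    Mz2 <- Mz * c1 + (nx * My - ny * Mx) * s1 + nz * dot * (1 - c1)
    Mx <- Mx2; My <- My2; Mz <- Mz2
  }
  rbind(Mx = Mx, My = My, Mz = Mz)
}

#' Inversion profile of a shaped pulse
#'
#' Integrates the Bloch equations for an isolated spin starting at `+z` and
#' reports the inversion efficiency `-Mz(final)/Mz(initial)` at each
#' offset: +1 is perfect inversion, -1 an untouched spin.
#'
#' @param shape A [pulse_shape()].
#' @param duration Pulse length (s).
#' @param peak_b1 Peak RF amplitude (Hz).
#' @param offsets_hz Offsets at which to evaluate (Hz).
#' @return Data frame with `offset_hz` and `efficiency`.
#' @export
inversion_profile <- function(shape, duration, peak_b1, offsets_hz) {
  stopifnot(all(is.finite(offsets_hz)))
  M <- bloch_profile(shape, duration, peak_b1, offsets_hz)
  data.frame(offset_hz = offsets_hz, efficiency = -M["Mz", ])
}

#' Width of the on-band region of an inversion profile
#'
#' The bandwidth is the width of the contiguous region around zero offset
#' whose inversion efficiency stays at or above `threshold` (default 0.8,
#' the package's bandwidth convention), with linear interpolation at the
#' band edges.
#'
#' @param profile A data frame from [inversion_profile()].
#' @param threshold Efficiency threshold.
#' @return Bandwidth in Hz.
#' @export
measure_bandwidth <- function(profile, threshold = 0.8) {
  off <- profile$offset_hz
  p <- profile$efficiency
  o <- order(off)
  off <- off[o]; p <- p[o]
  i0 <- which.min(abs(off))
  if (p[i0] < threshold)
    stop("profile does not reach the threshold at zero offset")
  lo <- i0; while (lo > 1 && p[lo - 1] >= threshold) lo <- lo - 1
  hi <- i0; while (hi < length(p) && p[hi + 1] >= threshold) hi <- hi + 1
  if (lo == 1 || hi == length(p))
    stop("profile does not span the band edges")
  f_lo <- off[lo - 1] + (off[lo] - off[lo - 1]) *
    (threshold - p[lo - 1]) / (p[lo] - p[lo - 1])
  f_hi <- off[hi] + (off[hi + 1] - off[hi]) *
    (threshold - p[hi]) / (p[hi + 1] - p[hi])
  f_hi - f_lo
}

#' Calibrate the peak B1 of a shape for a 180 degree rotation
#'
#' Deterministic golden-section search (relative tolerance 1e-3) of the
#' on-resonance inversion efficiency over a window around the analytic
#' flip-angle estimate `B1 = 1/(2 T mean(a))`.
#'
#' @param shape A [pulse_shape()].
#' @param duration Pulse length (s).
#' @return Peak B1 in Hz.
#' @export
calibrate_b1 <- function(shape, duration) {
  guess <- 1 / (2 * duration * mean(shape$samples$amplitude))
  f <- function(b) inversion_profile(shape, duration, b, 0)$efficiency
  opt <- stats::optimize(f, c(0.6 * guess, 1.6 * guess), maximum = TRUE,
                         tol = 1e-3 * guess)
  if (opt$objective < 0.9)
    stop("no usable inversion maximum found in the search window")
  opt$maximum
}

#' Bandwidth-duration product of a shape
#'
#' Calibrates the shape at the given duration, simulates its inversion
#' profile and returns `measure_bandwidth(...) * duration`, a dimensionless
#' constant for a given shape family.
#'
#' @inheritParams calibrate_b1
#' @param threshold Bandwidth threshold passed to [measure_bandwidth()].
#' @param n_offsets Number of profile points.
#' @return Named list with `peak_b1`, `bandwidth_hz` and `tbp`.
#' @export
time_bandwidth_product <- function(shape, duration, threshold = 0.8,
                                   n_offsets = 801) {
  b1 <- calibrate_b1(shape, duration)
  offs <- seq(-3 / duration, 3 / duration, length.out = n_offsets)
  prof <- inversion_profile(shape, duration, b1, offs)
  bw <- measure_bandwidth(prof, threshold)
  list(peak_b1 = b1, bandwidth_hz = bw, tbp = bw * duration)
}

#' Write / read a pulse shape as two-column text
#'
#' Plain text with a `# pulse_shape <name>` header line followed by
#' amplitude and phase (degrees) columns.
#'
#' @param shape A [pulse_shape()].
#' @param path File path.
#' @return `write_shape` returns `path` invisibly; `read_shape` returns the
#'   [pulse_shape()].
#' @export
write_shape <- function(shape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pulse_shape %s", shape$name), con)
  utils::write.table(format(shape$samples, digits = 17), con,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# pulse_shape ", lines[1]))
    stop("not a pulse_shape file (missing header): ", path)
  name <- sub("^# pulse_shape ", "", lines[1])
  df <- utils::read.table(text = lines[-1], header = TRUE)
  if (!all(c("amplitude", "phase") %in% names(df)))
    stop("malformed pulse_shape file: ", path)
  pulse_shape(df$amplitude, df$phase, name)
}
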