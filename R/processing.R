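# From chunked FIDs to calibrated spectra.

#' Free induction decay container
#'
#' @param samples Complex sample vector.
#' @param dwell Dwell time (s).
#' @param carrier_ppm Carrier position (ppm).
#' @param base_freq Larmor frequency (MHz).
#' @return An `nmr_fid` object.
#' @export
fid <- function(samples, dwell, carrier_ppm = 4.7, base_freq = 500) {
  stopifnot(length(samples) > 0, dwell > 0)
  structure(list(samples = as.complex(samples), dwell = dwell,
                 carrier_ppm = carrier_ppm, base_freq = base_freq),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d points, dwell %g us (aq %.4g ms)\n",
              length(x$samples), x$dwell * 1e6,
              length(x$samples) * x$dwell * 1e3))
  invisible(x)
}

#' Concatenate real-time chunks into a composite FID
#'
#' Joins the chunks in acquisition order after dropping `droppoints`
#' leading samples from each chunk (dead-time studies).
#'
#' @param cfid A `chunked_fid` from [run_sequence()].
#' @param droppoints Leading samples to drop per chunk.
#' @return An [fid()].
#' @export
concatenate_chunks <- function(cfid, droppoints = 0) {
  stopifnot(inherits(cfid, "chunked_fid"))
  lens <- lengths(cfid$chunks)
  if (droppoints >= min(lens)) stop("droppoints must be < chunk_points")
  smp <- unlist(lapply(cfid$chunks, function(s)
    if (droppoints > 0) s[-seq_len(droppoints)] else s))
  fid(smp, cfid$dwell, cfid$carrier_ppm, cfid$base_freq)
}

#' Assemble an interferogram-mode pure shift FID
#'
#' Takes one `chunked_fid` per pure shift increment (`t_ps` stepped by
#' `1/sw_ps`) and concatenates chunk `k` of record `k`, the
#' interferogram-based counterpart of real-time concatenation.
#'
#' @param records List of `chunked_fid` objects, one per increment, each
#'   holding at least as many chunks as there are records.
#' @param droppoints Leading samples to drop per chunk.
#' @return An [fid()].
#' @export
assemble_interferogram <- function(records, droppoints = 0) {
  stopifnot(length(records) >= 1)
  if (!all(vapply(records, inherits, logical(1), "chunked_fid")))
    stop("records must be chunked_fid objects")
  dw <- vapply(records, function(r) r$dwell, numeric(1))
  pat <- vapply(records, function(r)
    paste(lengths(r$chunks), collapse = ","), character(1))
  if (length(unique(dw)) > 1 || length(unique(pat)) > 1)
    stop("inconsistent increments: records differ in dwell or chunk layout")
  n <- length(records)
  chunks <- lapply(seq_len(n), function(k) {
    if (length(records[[k]]$chunks) < k)
      stop("missing record: increment ", k, " has too few chunks")
    records[[k]]$chunks[[k]]
  })
  concatenate_chunks(chunked_fid(chunks, dw[1], seed = records[[1]]$seed),
                     droppoints = droppoints)
}

apodize_vec <- function(v, dwell, window, gf1 = 0.085, shift = 90) {
  n <- length(v)
  tt <- (seq_len(n) - 1) * dwell
  w <- switch(window,
    none = rep(1, n),
    gaussian = exp(-tt^2 / gf1^2),
    sine_squared = {
      s <- shift * pi / 180
      sin(s + (pi - s) * tt / (n * dwell))^2
    },
    stop("unknown window: ", window))
  v * w
}

#' Apodize a FID
#'
#' `gaussian` multiplies by `exp(-t^2/gf1^2)` (value `1/e` at `t = gf1`);
#' `sine_squared` by a shifted sine-squared window (`shift = 90` degrees
#' gives the standard cosine-squared decay).
#'
#' @param x An [fid()].
#' @param window `"none"`, `"gaussian"`, or `"sine_squared"`.
#' @param gf1 Gaussian time constant (s).
#' @param shift Sine-squared shift (degrees).
#' @return The apodized [fid()].
#' @export
apodize <- function(x, window = c("none", "gaussian", "sine_squared"),
                    gf1 = 0.085, shift = 90) {
  window <- match.arg(window)
  stopifnot(inherits(x, "nmr_fid"), gf1 > 0)
  x$samples <- apodize_vec(x$samples, x$dwell, window, gf1, shift)
  x
}

#' 1D spectrum container
#'
#' Frequency axis ascending in Hz (offset from the carrier); ppm axes are
#' derived as `carrier_ppm + freq_hz / base_freq` and are conventionally
#' plotted decreasing left to right.
#'
#' @param intensity Complex spectrum values.
#' @param sw Spectral width (Hz).
#' @param carrier_ppm,base_freq Axis calibration.
#' @param ref_offset_hz Internal referencing correction already applied to
#'   the axis (Hz).
#' @return An `nmr_spectrum` object with elements `intensity` and
#'   `freq_hz`.
#' @export
spectrum_1d <- function(intensity, sw, carrier_ppm = 4.7, base_freq = 500,
                        ref_offset_hz = 0) {
  n <- length(intensity)
  freq <- (seq_len(n) - 1 - floor(n / 2)) * sw / n + ref_offset_hz
  structure(list(intensity = intensity, freq_hz = freq, sw = sw,
                 carrier_ppm = carrier_ppm, base_freq = base_freq,
                 ref_offset_hz = ref_offset_hz),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, sw %g Hz, carrier %g ppm\n",
              length(x$intensity), x$sw, x$carrier_ppm))
  invisible(x)
}

#' ppm axis of a spectrum
#'
#' @param spec An `nmr_spectrum`.
#' @return Numeric vector of ppm values aligned with `spec$intensity`.
#' @export
ppm_axis <- function(spec) spec$carrier_ppm + spec$freq_hz / spec$base_freq

#' Zero-fill and Fourier transform a FID
#'
#' The first point is halved before transformation (so the spectrum
#' baseline equals the mean rather than half the first point), the FID is
#' zero-filled to `target_points`, and the FFT uses the convention that a
#' signal `exp(+2 pi i nu t)` appears at `+nu` on the axis.
#'
#' @param x An [fid()].
#' @param target_points Zero-fill length (at least the FID length).
#' @param halve_first Halve the first point (standard; disable for
#'   Parseval checks).
#' @return An [spectrum_1d()].
#' @export
zero_fill_and_ft <- function(x, target_points = NULL, halve_first = TRUE) {
  stopifnot(inherits(x, "nmr_fid"))
  n <- length(x$samples)
  if (is.null(target_points)) target_points <- n
  if (target_points < n) stop("target_points must be >= FID length")
  s <- x$samples
  if (halve_first) s[1] <- s[1] * 0.5
  s <- c(s, complex(target_points - n))
  X <- stats::fft(s)
  # reorder so the axis runs -sw/2 .. +sw/2
  N <- target_points
  idx <- c((floor(N / 2) + 1):N, 1:floor(N / 2))
  spectrum_1d(X[idx], sw = 1 / x$dwell,
              carrier_ppm = x$carrier_ppm, base_freq = x$base_freq)
}

#' Shift the axis calibration of a spectrum
#'
#' Internal referencing: adds `delta_hz` to the frequency axis without
#' touching the data, correcting e.g. the systematic shift (order 2 Hz)
#' caused by short gradient stabilization delays.
#'
#' @param spec An `nmr_spectrum` (or `nmr_spectrum_2d`, where the shift
#'   applies to the direct axis).
#' @param delta_hz Axis correction (Hz).
#' @return The re-referenced spectrum.
#' @export
reference_shift <- function(spec, delta_hz) {
  if (inherits(spec, "nmr_spectrum_2d")) {
    spec$f2_hz <- spec$f2_hz + delta_hz
    spec$ref_offset_f2 <- spec$ref_offset_f2 + delta_hz
    return(spec)
  }
  stopifnot(inherits(spec, "nmr_spectrum"))
  spec$freq_hz <- spec$freq_hz + delta_hz
  spec$ref_offset_hz <- spec$ref_offset_hz + delta_hz
  spec
}

#' 2D Fourier transform of an HSQC data set
#'
#' Transforms the direct dimension of every t1 record, combines the
#' quadrature components (States, or Rance-Kay echo/antiecho where
#' `cos = (E + A)/2` and `sin = (E - A)/(2i)`), and transforms the
#' indirect dimension.  Optional apodization per dimension is applied
#' before zero-filling.
#'
#' @param h An `hsqc_data` from [run_hsqc()].
#' @param zf2,zf1 Zero-fill sizes for the direct / indirect dimensions
#'   (default: next power of two of twice the data size).
#' @param window_f1,window_f2 Apodization windows (see [apodize()]).
#' @param gf1 Gaussian time constant for the indirect dimension (s).
#' @return An `nmr_spectrum_2d`: complex matrix `intensity` indexed
#'   `[f1, f2]` plus axis vectors `f1_hz`, `f2_hz` and calibration fields.
#' @export
ft_2d <- function(h, zf2 = NULL, zf1 = NULL,
                  window_f1 = "gaussian", window_f2 = "none",
                  gf1 = 0.085) {
  stopifnot(inherits(h, "hsqc_data"))
  nt1 <- h$n_t1
  comps <- names(h$records[[1]])
  f2specs <- lapply(h$records, function(rec)
    lapply(rec, function(fd) {
      fd <- apodize(fd, window_f2, gf1 = gf1)
      zero_fill_and_ft(fd, zf2 %||% (2^ceiling(log2(2 * length(fd$samples)))))
    }))
  n2 <- length(f2specs[[1]][[1]]$intensity)
  if (h$echo_antiecho) {
    # Rance-Kay: cos = (E + A)/2, sin = (E - A)/(2i); then as States
    Z <- t(vapply(f2specs, function(sp) {
      co <- (sp$echo$intensity + sp$antiecho$intensity) / 2
      si <- (sp$echo$intensity - sp$antiecho$intensity) / (2i)
      co + 1i * si
    }, complex(n2)))
  } else {
    Z <- t(vapply(f2specs, function(sp)
      sp$cos$intensity + 1i * sp$sin$intensity, complex(n2)))
  }
  if (is.null(zf1)) zf1 <- 2^ceiling(log2(max(2 * nt1, 8)))
  dwell1 <- 1 / h$sw1
  M <- matrix(0i, zf1, n2)
  for (j in seq_len(n2)) {
    col <- apodize_vec(Z[, j], dwell1, window_f1, gf1 = gf1)
    col[1] <- col[1] * 0.5
    X <- stats::fft(c(col, complex(zf1 - nt1)))
    idx <- c((floor(zf1 / 2) + 1):zf1, 1:floor(zf1 / 2))
    M[, j] <- X[idx]
  }
  f2 <- f2specs[[1]][[1]]$freq_hz
  f1 <- (seq_len(zf1) - 1 - floor(zf1 / 2)) * h$sw1 / zf1
  structure(list(intensity = M, f1_hz = f1, f2_hz = f2,
                 sw1 = h$sw1, sw2 = f2specs[[1]][[1]]$sw,
                 carrier_ppm_f1 = h$carrier_ppm_f1,
                 base_freq_f1 = h$base_freq_f1,
                 carrier_ppm_f2 = f2specs[[1]][[1]]$carrier_ppm,
                 base_freq_f2 = f2specs[[1]][[1]]$base_freq,
                 ref_offset_f2 = 0),
            class = "nmr_spectrum_2d")
}

#' @export
print.nmr_spectrum_2d <- function(x, ...) {
  cat(sprintf("<nmr_spectrum_2d> %d x %d (f1 x f2), sw1 %g Hz, sw2 %g Hz\n",
              nrow(x$intensity), ncol(x$intensity), x$sw1, x$sw2))
  invisible(x)
}

#' Position of the 2D magnitude maximum
#'
#' @param spec2 An `nmr_spectrum_2d`.
#' @return List with `f1_hz`, `f2_hz` of the strongest magnitude point.
#' @export
peak_position_2d <- function(spec2) {
  A <- Mod(spec2$intensity)
  ij <- which(A == max(A), arr.ind = TRUE)[1, ]
  list(f1_hz = spec2$f1_hz[ij[1]], f2_hz = spec2$f2_hz[ij[2]],
       height = A[ij[1], ij[2]])
}
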