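# JCAMP-DX 5.00 export of 1D FIDs and spectra (NTUPLES subset, AFFN
# tables, untruncated %.17g values so round trips are lossless), plus a
# plain-text + JSON sidecar format for 2D spectra.

#' Write / read a 1D FID as JCAMP-DX
#'
#' Writes an NMR FID as a JCAMP-DX 5.00 NTUPLES record with AFFN data
#' tables for the real and imaginary pages.  Values are written at full
#' double precision, so `read_jcamp(write_jcamp(x))` reproduces the data
#' to better than 1e-12.
#'
#' @param x An [fid()].
#' @param path File path.
#' @param title Record title.
#' @return `write_jcamp` returns `path` invisibly; `read_jcamp` the
#'   [fid()].
#' @export
write_jcamp <- function(x, path, title = "pureshiftr FID") {
  stopifnot(inherits(x, "nmr_fid"))
  n <- length(x$samples)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("##TITLE= %s", title)
  w("##JCAMP-DX= 5.00")
  w("##DATA TYPE= NMR FID")
  w("##DATA CLASS= NTUPLES")
  w("##ORIGIN= pureshiftr")
  w("##OWNER= pureshiftr")
  w("##.OBSERVE FREQUENCY= %.17g", x$base_freq)
  w("##$CARRIER PPM= %.17g", x$carrier_ppm)
  w("##$DWELL SEC= %.17g", x$dwell)
  w("##NTUPLES= NMR FID")
  w("##VAR_NAME= TIME, FID/REAL, FID/IMAG")
  w("##VAR_DIM= %d, %d, %d", n, n, n)
  for (page in c("REAL", "IMAG")) {
    v <- if (page == "REAL") Re(x$samples) else Im(x$samples)
    w("##PAGE= N=%s", page)
    w("##DATA TABLE= (X++(Y..Y)), AFFN")
    for (i in seq(1, n, by = 4)) {
      j <- min(i + 3, n)
      w("%d %s", i - 1, paste(sprintf("%.17g", v[i:j]), collapse = " "))
    }
  }
  w("##END NTUPLES= NMR FID")
  w("##END=")
  invisible(path)
}

#' @rdname write_jcamp
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##TITLE=", lines[1]))
    stop(sprintf("parse error at line 1: not a JCAMP-DX file (%s)", path))
  if (!any(grepl("^##END=", lines)))
    stop("parse error: truncated JCAMP-DX file (missing ##END=): ", path)
  field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, fixed = FALSE)
    if (!length(hit)) stop("parse error: missing record ", key, " in ", path)
    as.numeric(sub(paste0("^", key, "=\\s*"), "", lines[hit[1]]))
  }
  base_freq <- field("##\\.OBSERVE FREQUENCY")
  carrier <- field("##\\$CARRIER PPM")
  dwell <- field("##\\$DWELL SEC")
  n <- as.integer(strsplit(sub("^##VAR_DIM=\\s*", "",
                               lines[grep("^##VAR_DIM=", lines)[1]]),
                           ",")[[1]][1])
  pages <- grep("^##PAGE= N=", lines)
  if (length(pages) != 2) stop("parse error: expected 2 data pages in ", path)
  get_page <- function(start) {
    out <- numeric(0)
    i <- start + 2
    while (i <= length(lines) && !grepl("^##", lines[i])) {
      vals <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      if (anyNA(vals))
        stop(sprintf("parse error at line %d: non-numeric data table entry", i))
      out <- c(out, vals[-1])
      i <- i + 1
    }
    out
  }
  re <- get_page(pages[1])
  im <- get_page(pages[2])
  if (length(re) != n || length(im) != n)
    stop(sprintf("parse error: data table length %d/%d does not match VAR_DIM %d",
                 length(re), length(im), n))
  fid(complex(real = re, imaginary = im), dwell, carrier, base_freq)
}

#' Write / read a 2D spectrum as text matrix plus JSON metadata
#'
#' `basename.json` holds the axis calibration and processing metadata;
#' `basename.re.tsv` / `basename.im.tsv` the real and imaginary parts.
#'
#' @param spec2 An `nmr_spectrum_2d`.
#' @param basename Path prefix (without extension).
#' @return `write_spectrum_2d` returns `basename` invisibly;
#'   `read_spectrum_2d` the `nmr_spectrum_2d`.
#' @export
write_spectrum_2d <- function(spec2, basename) {
  stopifnot(inherits(spec2, "nmr_spectrum_2d"))
  meta <- spec2[setdiff(names(spec2), "intensity")]
  meta$dim <- dim(spec2$intensity)
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(format(Re(spec2$intensity), digits = 17),
                     paste0(basename, ".re.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(format(Im(spec2$intensity), digits = 17),
                     paste0(basename, ".im.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(basename)
}

#' @rdname write_spectrum_2d
#' @export
read_spectrum_2d <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  re <- as.matrix(utils::read.table(paste0(basename, ".re.tsv"), sep = "\t"))
  im <- as.matrix(utils::read.table(paste0(basename, ".im.tsv"), sep = "\t"))
  out <- meta[setdiff(names(meta), "dim")]
  out$intensity <- matrix(complex(real = as.numeric(re),
                                  imaginary = as.numeric(im)),
                          nrow = meta$dim[1])
  class(out) <- "nmr_spectrum_2d"
  out
}
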