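# YAML round-tripping of spin systems and run configurations, and the
# provenance block every run emits.

# YAML 1.1 parses a bare N/n/Y/y as a boolean, which collides with
# nitrogen spin labels; keep single letters as strings, resolve the rest.
read_yaml_guarded <- function(path) {
  keep <- function(x) {
    if (x %in% c("y", "Y", "n", "N")) x
    else toupper(x) %in% c("TRUE", "YES", "ON")
  }
  yaml::read_yaml(path, handlers = list("bool#yes" = keep, "bool#no" = keep))
}

#' Write / read a spin system as YAML
#'
#' The schema has top-level keys `spins` (list of label / isotope /
#' shift_ppm / T2 / T1 / role), `couplings` (list of a / b / J in Hz),
#' `base_freq` (MHz per isotope) and `carrier_ppm`.
#'
#' @param sys A [spin_system()].
#' @param path File path.
#' @param strict Passed to [spin_system()] on reading.
#' @return `write_spin_system` returns `path` invisibly; `read_spin_system`
#'   the [spin_system()].
#' @export
write_spin_system <- function(sys, path) {
  stopifnot(inherits(sys, "spin_system"))
  sp <- sys$spins
  spins <- lapply(seq_len(nrow(sp)), function(i) {
    x <- list(label = sp$label[i], isotope = sp$isotope[i],
              shift_ppm = sp$shift_ppm[i], T2 = sp$T2[i], role = sp$role[i])
    if (!is.na(sp$T1[i])) x$T1 <- sp$T1[i]
    x
  })
  nz <- which(upper.tri(sys$J) & sys$J != 0, arr.ind = TRUE)
  couplings <- lapply(seq_len(nrow(nz)), function(k)
    list(a = rownames(sys$J)[nz[k, 1]], b = colnames(sys$J)[nz[k, 2]],
         J = sys$J[nz[k, 1], nz[k, 2]]))
  obj <- list(spins = spins, couplings = couplings,
              base_freq = as.list(sys$base_freq),
              carrier_ppm = as.list(sys$carrier_ppm))
  writeLines(yaml::as.yaml(obj, precision = 17), path)
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_spin_system <- function(path, strict = TRUE) {
  obj <- read_yaml_guarded(path)
  for (key in c("spins", "base_freq", "carrier_ppm"))
    if (is.null(obj[[key]]))
      stop("spin system file missing field: ", key)
  spins <- do.call(rbind, lapply(obj$spins, function(x) {
    for (key in c("label", "isotope", "shift_ppm"))
      if (is.null(x[[key]]))
        stop("spin entry missing field: spins/", key)
    spin(x$label, x$isotope, x$shift_ppm,
         T2 = x$T2 %||% Inf, T1 = x$T1 %||% NA_real_,
         role = x$role %||% "passive")
  }))
  n <- nrow(spins)
  J <- matrix(0, n, n, dimnames = list(spins$label, spins$label))
  for (cp in obj$couplings) {
    if (is.null(cp$a) || is.null(cp$b) || is.null(cp$J))
      stop("coupling entry needs fields a, b, J")
    J[cp$a, cp$b] <- J[cp$b, cp$a] <- cp$J
  }
  spin_system(spins, J,
              base_freq = unlist(obj$base_freq),
              carrier_ppm = unlist(obj$carrier_ppm),
              strict = strict)
}

#' Read and validate a run configuration
#'
#' A run configuration is a YAML document with sections `spin_system`
#' (inline schema or a `file:` reference), `element`, `acquisition`,
#' optional `hsqc`, `processing`, `analysis`, and a top-level `seed`.
#' Validation reports the path of the offending field.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with constructed package objects
#'   (`$sys`, `$element`, `$acquisition`).
#' @export
read_run_config <- function(path) {
  cfg <- read_yaml_guarded(path)
  fail <- function(field, msg) stop(sprintf("config %s: %s", field, msg),
                                    call. = FALSE)
  if (is.null(cfg$spin_system)) fail("spin_system", "is required")
  sys <- if (!is.null(cfg$spin_system$file)) {
    fp <- cfg$spin_system$file
    if (!file.exists(fp))
      fp <- file.path(dirname(path), cfg$spin_system$file)
    if (!file.exists(fp)) fail("spin_system/file", "file not found")
    read_spin_system(fp)
  } else if (!is.null(cfg$spin_system$fixture)) {
    generate_fixture(cfg$spin_system$fixture,
                     n_residues = cfg$spin_system$n_residues %||% 5,
                     seed = cfg$seed %||% 1)
  } else {
    tmp <- tempfile(fileext = ".yaml")
    writeLines(yaml::as.yaml(cfg$spin_system, precision = 17), tmp)
    on.exit(unlink(tmp))
    read_spin_system(tmp)
  }
  el <- NULL
  if (!is.null(cfg$element)) {
    if (is.null(cfg$element$kind)) fail("element/kind", "is required")
    if (!cfg$element$kind %in% c("bird", "bashd", "gbird", "gbashd", "ideal"))
      fail("element/kind", paste("unknown kind", cfg$element$kind))
    args <- cfg$element[intersect(names(cfg$element),
                                  names(formals(element_spec)))]
    el <- do.call(element_spec, args)
  }
  acq <- NULL
  if (!is.null(cfg$acquisition)) {
    for (key in c("sw", "total_points"))
      if (is.null(cfg$acquisition[[key]]))
        fail(paste0("acquisition/", key), "is required")
    acq <- acquisition_plan(cfg$acquisition$sw, cfg$acquisition$total_points,
                            cfg$acquisition$n_chunks %||% 1, element = el,
                            droppoints = cfg$acquisition$droppoints %||% 0)
  }
  structure(list(raw = cfg, sys = sys, element = el, acquisition = acq,
                 seed = cfg$seed %||% 1,
                 processing = cfg$processing, analysis = cfg$analysis,
                 path = path),
            class = "run_config")
}

#' Provenance block for a run
#'
#' MD5 hash of the configuration file, the seed, and package/R versions;
#' attach this to every output so runs are reproducible.
#'
#' @param config_path Path of the configuration file (or `NULL`).
#' @param seed Seed used.
#' @return Named list.
#' @export
provenance_block <- function(config_path = NULL, seed = NA) {
  list(
    config = if (!is.null(config_path)) basename(config_path) else NA,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA,
    seed = seed,
    package = as.character(utils::packageVersion("pureshiftr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
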