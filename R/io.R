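#' Read / write an FID as a self-describing container
#'
#' The container is a JSON document holding the complex samples (separate
#' real and imaginary arrays) together with the metadata that makes an FID
#' interpretable on its own: dwell time, reference frequency, ppm offset of
#' the acquisition center, and the synthesis noise sigma and seed when known.
#'
#' @param f An [fid()].
#' @param path File path.
#' @return `write_fid` returns `path` invisibly; `read_fid` an [fid()].
#' @export
write_fid <- function(f, path) {
  doc <- list(format = "hpmrsim-fid", version = 1L,
              dwell_ms = f$dwell_ms, ref_mhz = f$ref_mhz,
              ppm_center = f$ppm_center, noise_sigma = f$noise_sigma,
              seed = f$seed, re = Re(f$samples), im = Im(f$samples))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "hpmrsim-fid")
    stop_invalid("not an hpmrsim FID container: ", path)
  fid(complex(real = doc$re, imaginary = doc$im), dwell_ms = doc$dwell_ms,
      ref_mhz = doc$ref_mhz, ppm_center = doc$ppm_center,
      noise_sigma = if (is.null(doc$noise_sigma)) NA_real_ else doc$noise_sigma,
      seed = if (is.null(doc$seed)) NA_integer_ else doc$seed)
}

#' Write a simulated profile or tabular result as text
#'
#' @param x A data.frame (e.g. a [slice_profile()] or overlap report).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_txt <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

run_config_schema <- function() {
  list(
    seed = NULL,
    pulses = c("hs_duration_ms", "hs_beta", "hs_n", "hs_bandwidth_hz",
               "exc_bandwidth_hz", "exc_sharpness", "ref_bandwidth_hz"),
    sequence = c("tr_ms", "te_ms", "flip", "n_points", "bandwidth_ppm",
                 "frequency_mhz", "zero_fill", "tau_lower_bounds_ms"),
    plan = c("file", "roles", "allow_overlap"),
    ledger = c("t1_s", "q_afp", "q_slr", "resolution_mm", "flip"),
    csi = c("nx", "ny", "flip", "tr_ms", "t1_s", "up_first"),
    fit = c("n_peaks", "background_ppm", "zero_fill", "line_broaden_hz"),
    ph = c("pKa", "delta_acid", "delta_base", "n_compartments", "c1_ppm")
  )
}

#' Read and validate a run configuration file
#'
#' The configuration is structured YAML with sections `pulses`, `sequence`,
#' `plan`, `ledger`, `csi`, `fit`, `ph` plus a global `seed`. Unknown
#' sections or keys are rejected with the offending field path; a few typed
#' constraints (flip angles, positive timings) are enforced here so that
#' command-line runs fail early with a named field.
#'
#' @param path Path to a YAML configuration file.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- run_config_schema()
  for (sec in names(cfg)) {
    if (!sec %in% names(schema))
      stop_invalid("unknown configuration section: ", sec)
    if (sec == "seed") next
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      stop_invalid("unknown configuration key: ", sec, ".", bad[1])
  }
  check_range <- function(section, key, lo, hi, lo_open = TRUE) {
    v <- cfg[[section]][[key]]
    if (!is.null(v) && (!is.numeric(v) ||
                        (if (lo_open) any(v <= lo) else any(v < lo)) ||
                        any(v > hi)))
      stop_invalid("invalid value for ", section, ".", key,
                   ": must be in (", lo, ", ", hi, "]")
    invisible(NULL)
  }
  check_range("sequence", "flip", 0, 90)
  check_range("ledger", "flip", 0, 180)
  check_range("csi", "flip", 0, 90)
  check_range("sequence", "tr_ms", 0, Inf)
  check_range("ledger", "q_afp", 0, 1, lo_open = FALSE)
  check_range("ledger", "q_slr", 0, 1, lo_open = FALSE)
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)))
    stop_invalid("invalid value for seed: must be an integer")
  structure(cfg, class = c("run_config", "list"))
}
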