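# Readers and writers for the plain-text interchange formats.
# All CSVs are UTF-8 with '.' decimal and a header row.

read_csv_checked <- function(path, cols, what) {
  if (!file.exists(path)) {
    abort_data(sprintf("%s file not found: %s", what, path))
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(cnd) {
      abort_data(sprintf("could not parse %s file %s: %s", what, path,
                         conditionMessage(cnd)))
    })
  check_columns(data, cols, sprintf("%s file `%s`", what, path))
  data
}

#' Read and write the package's CSV dialects
#'
#' * Sweep CSV: `frequency_hz, g_prime_pa, g_double_prime_pa`.
#' * Relaxation CSV: `time_s, modulus_pa`, or `time_s, stress_pa` together
#'   with `step_strain` (the declared step-strain amplitude, dimensionless),
#'   in which case stress is converted to relaxation modulus on read.
#' * Cine contour CSV: `frame_index, time_s, point_index, x_mm, y_mm` and
#'   optionally `surface` (`endo`/`epi`).
#' * Zone label CSV: `segment_index, zone`.
#'
#' @param path File path.
#' @param step_strain Declared step-strain amplitude for stress-valued
#'   relaxation files.
#' @return A tibble in the corresponding in-memory layout.
#' @name gelstrain_io
NULL

#' @rdname gelstrain_io
#' @export
read_sweep_csv <- function(path) {
  read_csv_checked(path, c("frequency_hz", "g_prime_pa",
                           "g_double_prime_pa"), "sweep")
}

#' @rdname gelstrain_io
#' @export
read_relaxation_csv <- function(path, step_strain = NULL) {
  data <- read_csv_checked(path, "time_s", "relaxation")
  if ("modulus_pa" %in% names(data)) {
    return(data[, c("time_s", "modulus_pa")])
  }
  if ("stress_pa" %in% names(data)) {
    if (is.null(step_strain)) {
      abort_data(
        "stress-valued relaxation data need a declared `step_strain`.")
    }
    check_number(step_strain, "step_strain", positive = TRUE)
    out <- data[, "time_s"]
    out$modulus_pa <- data$stress_pa / step_strain
    return(out)
  }
  abort_data(sprintf(
    "relaxation file `%s` needs a `modulus_pa` or `stress_pa` column.",
    path))
}

#' @rdname gelstrain_io
#' @export
read_cine_csv <- function(path) {
  read_csv_checked(path, c("frame_index", "time_s", "point_index", "x_mm",
                           "y_mm"), "cine")
}

#' @rdname gelstrain_io
#' @export
read_zone_labels_csv <- function(path) {
  labels <- read_csv_checked(path, c("segment_index", "zone"), "zone label")
  bad <- setdiff(unique(labels$zone), c("infarct", "border", "remote"))
  if (length(bad) > 0) {
    abort_data(sprintf("unknown zone label(s): %s.",
                       paste(bad, collapse = ", ")))
  }
  labels
}

# JSON writer shared by the pipeline entry points; deterministic (no
# timestamps) so identical configs yield byte-identical reports.
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
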