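# End-to-end entry points: formulation design and strain analysis runs.
# Configuration is a JSON file or an equivalent named list; structured
# results are written as JSON, tabular results as tidy CSV.  Progress is
# reported to standard error so stdout stays machine-readable.

load_config <- function(config, required, what) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_gelstrain(sprintf("config file not found: %s", config),
                      "gelstrain_config_error")
    }
    config <- tryCatch(
      jsonlite::read_json(config, simplifyVector = TRUE),
      error = function(cnd) {
        abort_gelstrain(sprintf("malformed JSON config %s: %s", config,
                                conditionMessage(cnd)),
                        "gelstrain_config_error")
      })
  }
  if (!is.list(config)) {
    abort_gelstrain(sprintf("%s config must be a list or a JSON file path.",
                            what),
                    "gelstrain_config_error")
  }
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort_gelstrain(sprintf("%s config is missing field(s): %s.", what,
                            paste(missing, collapse = ", ")),
                    "gelstrain_config_error", missing_fields = missing)
  }
  config
}

log_info <- function(...) {
  message(sprintf(...))
}

#' Run the formulation-design pipeline
#'
#' Reads a heart specification, selects a heart-rate-matched formulation
#' via [match_formulation()] against [default_calibration()], and writes
#' `design.json` (machine-readable result) and `design_summary.txt` to the
#' output directory.  Outputs carry no timestamps, so reruns of the same
#' config are byte-identical.
#'
#' @param config A named list or path to a JSON file with fields `species`,
#'   `g_myo_pa`, `h_myo_mm`, `h_graft_mm`, `rate_band_hz` (length-2), and
#'   optionally `out_dir` (default `"."`) and `egcg_mM`.
#' @return The [match_formulation()] result, invisibly.
#' @examples
#' cfg <- list(species = "rat", g_myo_pa = 5000, h_myo_mm = 2,
#'             h_graft_mm = 0.3, rate_band_hz = c(3.5, 4.5),
#'             out_dir = tempdir())
#' run_design(cfg)
#' @export
run_design <- function(config) {
  cfg <- load_config(config, c("species", "g_myo_pa", "h_myo_mm",
                               "h_graft_mm", "rate_band_hz"), "design")
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  heart <- heart_spec(cfg$species, cfg$g_myo_pa, cfg$h_myo_mm,
                      cfg$h_graft_mm, as.numeric(cfg$rate_band_hz))
  log_info("gelstrain %s | design run for species '%s', band [%g, %g] Hz",
           as.character(utils::packageVersion("gelstrain")), heart$species,
           heart$rate_band_hz[1], heart$rate_band_hz[2])
  result <- match_formulation(heart)
  modes <- formulation_to_modes(
    result[, c("gtn_wt_percent", "fpba_fraction")])
  report <- list(
    species = result$species,
    formulation = list(gtn_wt_percent = result$gtn_wt_percent,
                       fpba_fraction = result$fpba_fraction,
                       egcg_mM = cfg$egcg_mM %||% 0),
    f_gp_hz = result$f_gp_hz,
    g_gp_pa = result$g_gp_pa,
    within_band = result$within_band,
    target_modulus_pa = result$target_modulus_pa,
    modes = purrr::pmap(modes, function(modulus_pa, tau_s) {
      list(modulus_pa = modulus_pa, tau_s = tau_s)
    }),
    characteristic_time_s =
      sum(modes$modulus_pa * modes$tau_s) / sum(modes$modulus_pa),
    heart = list(species = heart$species, g_myo_pa = heart$g_myo_pa,
                 h_myo_mm = heart$h_myo_mm, h_graft_mm = heart$h_graft_mm,
                 rate_band_hz = heart$rate_band_hz))
  write_report_json(report, file.path(out_dir, "design.json"))
  writeLines(c(
    sprintf("Heart-rate-matched design for %s", result$species),
    sprintf("  formulation : %g wt%% gelatin, FPBA fraction %g",
            result$gtn_wt_percent, result$fpba_fraction),
    sprintf("  gel point   : %.4g Hz, %.4g Pa", result$f_gp_hz,
            result$g_gp_pa),
    sprintf("  within band : %s", result$within_band)),
    file.path(out_dir, "design_summary.txt"))
  log_info("design written to %s", file.path(out_dir, "design.json"))
  invisible(result)
}

#' Run the strain-mapping pipeline
#'
#' Reads a cine contour CSV (and optional zone labels), runs
#' [analyze_cine()], and writes `strain_map.json` (summary: reference and
#' end-systolic frames, maximum peak strain differential, its boundary,
#' and zone means at end-systole when labels are given) plus
#' `strain_segments.csv` (the tidy per-frame per-segment table).
#'
#' @param config A named list or path to a JSON file with fields `cine`
#'   (contour CSV path) and optionally `labels` (zone CSV path),
#'   `n_segments` (default 24), `reference_angle_deg` (default 0) and
#'   `out_dir` (default `"."`).
#' @return The `strain_map`, invisibly.
#' @export
run_strain <- function(config) {
  cfg <- load_config(config, "cine", "strain")
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cine <- read_cine_csv(cfg$cine)
  scheme <- segmentation_scheme(
    n_segments = cfg$n_segments %||% 24,
    reference_angle = (cfg$reference_angle_deg %||% 0) * pi / 180)
  log_info("gelstrain %s | strain run on %s (%d segments)",
           as.character(utils::packageVersion("gelstrain")), cfg$cine,
           scheme$n_segments)
  sm <- analyze_cine(cine, scheme)

  peak <- sm$differentials[
    which.max(sm$differentials$delta_epsilon_cc_pct), ]
  summary <- list(
    n_frames = sm$n_frames,
    n_segments = scheme$n_segments,
    reference_frame_index = sm$reference_frame_index,
    end_systole_index = sm$end_systole_index,
    max_peak_strain_differential_pct = peak$delta_epsilon_cc_pct,
    max_differential_boundary_index = peak$boundary_index,
    max_differential_frame_index = peak$frame_index)
  if (!is.null(cfg$labels)) {
    labels <- read_zone_labels_csv(cfg$labels)
    es <- sm$strains[sm$strains$frame_index == sm$end_systole_index, ]
    es <- es[order(es$segment_index), ]
    labels <- labels[order(labels$segment_index), ]
    if (!identical(as.integer(labels$segment_index),
                   as.integer(es$segment_index))) {
      abort_data("zone labels must cover every segment exactly once.")
    }
    zm <- zone_mean_strain(es$epsilon_cc_pct, labels$zone)
    summary$zone_mean_strain_pct <-
      stats::setNames(as.list(zm$mean_strain_pct), zm$zone)
  }
  write_report_json(summary, file.path(out_dir, "strain_map.json"))
  readr::write_csv(tidy(sm), file.path(out_dir, "strain_segments.csv"))
  log_info("strain map written to %s", file.path(out_dir, "strain_map.json"))
  invisible(sm)
}
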