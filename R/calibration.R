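#' Default gel-point calibration for the dual-boronate gelatin hydrogel
#'
#' The gel-point frequency of the gelatin--phenylboronate network is set by
#' the ratio of the fluorinated crosslinker (FPBA, slow exchange) to the
#' plain one (PBA, fast exchange), while the gel-point modulus is set
#' independently by the gelatin weight fraction.  This calibration encodes
#' the measured design points of that system:
#'
#' * frequency knots (FPBA fraction -> \eqn{f_{GP}}, Hz):
#'   `0.0 -> 6.0`, `0.2 -> 4.0`, `0.6 -> 1.3`, `1.0 -> 0.3`;
#' * modulus knots (gelatin wt% -> \eqn{G'_{GP}}, Pa):
#'   `15 -> 1300`, `20 -> 2500`;
#' * an advertised tunable modulus range of 500--2500 Pa;
#' * a species design table with the two selected recipes (rat:
#'   15 wt%, FPBA fraction 0.2, target 1300 Pa; pig: 20 wt%, fraction 0.6,
#'   target 2500 Pa) together with the myocardial stiffness and wall/graft
#'   thicknesses they were chosen for.
#'
#' The pure-PBA endpoint is reported in the source data as "~6 Hz"; it is
#' treated as exactly 6.0 Hz here and the approximation is recorded in the
#' calibration's `notes` field.
#'
#' @return A list of class `calibration_map` with elements
#'   `frequency_knots` (tibble: `fpba_fraction`, `f_gp_hz`),
#'   `modulus_knots` (tibble: `gtn_wt_percent`, `g_gp_pa`),
#'   `modulus_range_pa`, `design_table` and `notes`.
#' @examples
#' default_calibration()$frequency_knots
#' @export
default_calibration <- function() {
  structure(
    list(
      frequency_knots = tibble(
        fpba_fraction = c(0.0, 0.2, 0.6, 1.0),
        f_gp_hz = c(6.0, 4.0, 1.3, 0.3)),
      modulus_knots = tibble(
        gtn_wt_percent = c(15, 20),
        g_gp_pa = c(1300, 2500)),
      modulus_range_pa = c(500, 2500),
      design_table = tibble(
        species = c("rat", "pig"),
        gtn_wt_percent = c(15, 20),
        fpba_fraction = c(0.2, 0.6),
        target_modulus_pa = c(1300, 2500),
        g_myo_pa = c(5000, 5000),
        h_myo_mm = c(2, 9),
        h_graft_mm = c(0.3, 1)),
      notes = "pure-PBA endpoint reported as ~6 Hz; calibrated as 6.0 Hz"),
    class = "calibration_map")
}

validate_calibration <- function(calibration) {
  if (!inherits(calibration, "calibration_map")) {
    abort_domain("`calibration` must be a `calibration_map`.")
  }
  fk <- calibration$frequency_knots
  mk <- calibration$modulus_knots
  if (nrow(fk) < 2 || any(diff(fk$fpba_fraction) <= 0) ||
      any(diff(fk$f_gp_hz) >= 0)) {
    abort_domain(
      "frequency knots must be strictly decreasing in FPBA fraction.")
  }
  if (nrow(mk) < 2 || any(diff(mk$gtn_wt_percent) <= 0) ||
      any(diff(mk$g_gp_pa) <= 0)) {
    abort_domain("modulus knots must be strictly increasing in wt%.")
  }
  invisible(calibration)
}

#' Specify a hydrogel formulation
#'
#' @param gtn_wt_percent Gelatin weight percent, in (0, 100).
#' @param fpba_fraction FPBA / (FPBA + PBA) crosslinker fraction, in
#'   \[0, 1\].
#' @param egcg_mM EGCG drug loading, mM (>= 0).  Loadings above 5 mM alter
#'   the gel mechanics and trigger a warning; the calibration assumes the
#'   mechanics-neutral regime.
#' @return A one-row tibble with the three fields.
#' @examples
#' formulation(15, 0.2)
#' @export
formulation <- function(gtn_wt_percent, fpba_fraction, egcg_mM = 0) {
  check_number(gtn_wt_percent, "gtn_wt_percent", positive = TRUE)
  if (gtn_wt_percent >= 100) {
    abort_domain("`gtn_wt_percent` must be in (0, 100).")
  }
  check_number(fpba_fraction, "fpba_fraction", nonnegative = TRUE)
  if (fpba_fraction > 1) {
    abort_domain("`fpba_fraction` must be in [0, 1].")
  }
  check_number(egcg_mM, "egcg_mM", nonnegative = TRUE)
  if (egcg_mM > 5) {
    warn(sprintf(
      "EGCG loading of %g mM exceeds 5 mM; hydrogel mechanics may deviate from the calibration.",
      egcg_mM), class = "gelstrain_egcg_warning")
  }
  tibble(gtn_wt_percent = gtn_wt_percent, fpba_fraction = fpba_fraction,
         egcg_mM = egcg_mM)
}

clamp_to_hull <- function(x, lo, hi, name, strict) {
  out_of_hull <- x < lo | x > hi
  if (any(out_of_hull)) {
    msg <- sprintf(
      "`%s` outside the calibrated range [%g, %g]; estimate clamped.",
      name, lo, hi)
    if (strict) {
      abort_gelstrain(sub("; estimate clamped.", ".", msg, fixed = TRUE),
                      "gelstrain_extrapolation_error")
    }
    warn(msg, class = "gelstrain_extrapolation_warning")
    x <- pmin(pmax(x, lo), hi)
  }
  x
}

freq_interpolator <- function(calibration) {
  fk <- calibration$frequency_knots
  # monotone piecewise-cubic (Fritsch-Carlson) on (fraction, log f):
  # exact at knots and shape-preserving with only four measured points
  splinefun(fk$fpba_fraction, log(fk$f_gp_hz), method = "monoH.FC")
}

#' Predict the gel point of a formulation from a calibration
#'
#' Gel-point frequency is obtained by monotone piecewise-cubic interpolation
#' of \eqn{\log f_{GP}} against the FPBA fraction through the frequency
#' knots; gel-point modulus by linear interpolation of the modulus knots
#' against gelatin wt%.  Both interpolants pass exactly through the knots,
#' and the two coordinates are independent: wt% never moves the predicted
#' frequency and the crosslinker ratio never moves the predicted modulus.
#'
#' @param formulations A data frame with columns `gtn_wt_percent` and
#'   `fpba_fraction` (one row per formulation), e.g. from [formulation()].
#' @param calibration A `calibration_map`, by default
#'   [default_calibration()].
#' @param strict If `TRUE`, formulations outside the calibrated knot hull
#'   signal a `gelstrain_extrapolation_error`; otherwise they are clamped to
#'   the hull with a `gelstrain_extrapolation_warning`.
#' @return The input tibble with `f_gp_hz` and `g_gp_pa` columns appended.
#' @examples
#' predict_gel_point(formulation(15, 0.2)) # 4 Hz, 1300 Pa
#' @export
predict_gel_point <- function(formulations,
                              calibration = default_calibration(),
                              strict = FALSE) {
  check_columns(formulations, c("gtn_wt_percent", "fpba_fraction"),
                "`formulations`")
  validate_calibration(calibration)
  fk <- calibration$frequency_knots
  mk <- calibration$modulus_knots
  frac <- clamp_to_hull(formulations$fpba_fraction,
                        min(fk$fpba_fraction), max(fk$fpba_fraction),
                        "fpba_fraction", strict)
  wt <- clamp_to_hull(formulations$gtn_wt_percent,
                      min(mk$gtn_wt_percent), max(mk$gtn_wt_percent),
                      "gtn_wt_percent", strict)
  out <- as_tibble(formulations)
  out$f_gp_hz <- exp(freq_interpolator(calibration)(frac))
  out$g_gp_pa <- approx(mk$gtn_wt_percent, mk$g_gp_pa, xout = wt)$y
  out
}

# Separation between the fast (PBA-like) and slow (FPBA-like) mode times in
# constructed spectra.  A two-mode Maxwell model keeps a unique G' = G''
# crossover for every weight split as long as the time ratio stays below
# ~12; beyond that a fold appears in which some weights produce three
# crossings and a band of crossover frequencies becomes unreachable.
MODE_TIME_RATIO <- 10

#' Construct a two-mode Maxwell spectrum realizing a formulation's gel point
#'
#' The two dynamic bond populations are represented as two Maxwell modes.
#' The mode weights follow the recipe directly -- a fraction `frac` of the
#' crosslinks are the slow (fluorinated) type, so the slow mode carries
#' weight `frac` and the fast mode `1 - frac` -- while the two relaxation
#' times keep a fixed 10:1 separation and are scaled jointly, by 1-D root
#' finding on the analytic crossover, until the spectrum's gel-point
#' frequency equals the calibrated prediction.  The total stiffness is then
#' scaled so the crossover modulus matches too.  The 10:1 time separation
#' is the largest (round) ratio for which a two-mode Maxwell model is
#' guaranteed a unique crossover at every weight split; wider separations
#' develop a fold with three G' = G'' crossings for intermediate weights,
#' which would make the gel point ill-defined.
#'
#' @param formulation_row A one-row data frame with `gtn_wt_percent` and
#'   `fpba_fraction`, e.g. from [formulation()].
#' @inheritParams predict_gel_point
#' @return A [maxwell_spectrum()] whose [find_gel_point()] on a densely
#'   sampled noiseless sweep reproduces [predict_gel_point()] to relative
#'   1e-6.  At the pure endpoints (fraction 0 or 1) a single mode is
#'   returned whose relaxation time is exactly the printed pure-component
#'   crossover time (`1/(2 pi f)` at 6.0 and 0.3 Hz respectively).
#' @examples
#' formulation_to_modes(formulation(15, 0.2))
#' @export
formulation_to_modes <- function(formulation_row,
                                 calibration = default_calibration(),
                                 strict = FALSE) {
  check_columns(formulation_row, c("gtn_wt_percent", "fpba_fraction"),
                "`formulation_row`")
  if (nrow(formulation_row) != 1) {
    abort_domain("`formulation_row` must have exactly one row.")
  }
  validate_calibration(calibration)
  fk <- calibration$frequency_knots
  f_fast <- max(fk$f_gp_hz)   # pure PBA endpoint (fraction 0)
  f_slow <- min(fk$f_gp_hz)   # pure FPBA endpoint (fraction 1)

  target <- predict_gel_point(formulation_row, calibration, strict = strict)
  f_star <- target$f_gp_hz
  g_star <- target$g_gp_pa
  frac <- formulation_row$fpba_fraction

  if (frac <= 0 || frac >= 1) {
    tau <- 1 / (2 * pi * if (frac <= 0) f_fast else f_slow)
    # single-mode crossover modulus is G0/2
    return(maxwell_spectrum(2 * g_star, tau))
  }

  # crossover frequency of the unit-time spectrum; scaling both times by
  # lambda scales the crossover by 1/lambda
  unit <- maxwell_spectrum(c(1 - frac, frac), c(1, MODE_TIME_RATIO))
  gap <- function(log_f) {
    m <- complex_moduli(unit, exp(log_f))
    m$g_prime_pa - m$g_double_prime_pa
  }
  root <- tryCatch(
    uniroot(gap, interval = log(c(1e-6, 1e3)), tol = 1e-13),
    error = function(cnd) {
      abort_gelstrain(
        sprintf(
          "could not bracket the crossover of the unit spectrum for target %.4g Hz.",
          f_star),
        "gelstrain_construction_error")
    })
  f_unit <- exp(root$root)
  taus <- c(1, MODE_TIME_RATIO) * (f_unit / f_star)
  scaled <- maxwell_spectrum(c(1 - frac, frac), taus)
  scale <- g_star / complex_moduli(scaled, f_star)$g_prime_pa
  maxwell_spectrum(scaled$modulus_pa * scale, scaled$tau_s)
}

#' Specify the target heart for patch design
#'
#' @param species Species label (`"rat"` and `"pig"` have measured design
#'   points in [default_calibration()]).
#' @param g_myo_pa Myocardial storage modulus, Pa.
#' @param h_myo_mm Ventricular wall thickness, mm.
#' @param h_graft_mm Intended graft (patch) thickness, mm.
#' @param rate_band_hz Length-2 numeric, the acceptable heart-rate band in
#'   Hz (lower <= upper).
#' @return A list of class `heart_spec`.
#' @examples
#' heart_spec("rat", 5000, 2, 0.3, c(3.5, 4.5))
#' @export
heart_spec <- function(species, g_myo_pa, h_myo_mm, h_graft_mm,
                       rate_band_hz) {
  if (!is.character(species) || length(species) != 1L || is.na(species)) {
    abort_domain("`species` must be a single string.")
  }
  check_number(g_myo_pa, "g_myo_pa", positive = TRUE)
  check_number(h_myo_mm, "h_myo_mm", positive = TRUE)
  check_number(h_graft_mm, "h_graft_mm", positive = TRUE)
  check_numeric_vector(rate_band_hz, "rate_band_hz", positive = TRUE,
                       min_length = 2L)
  if (length(rate_band_hz) != 2L || rate_band_hz[1] > rate_band_hz[2]) {
    abort_domain("`rate_band_hz` must be c(lower, upper) with lower <= upper.")
  }
  structure(list(species = species, g_myo_pa = g_myo_pa,
                 h_myo_mm = h_myo_mm, h_graft_mm = h_graft_mm,
                 rate_band_hz = rate_band_hz),
            class = "heart_spec")
}

#' Select a heart-rate-matched formulation for a target heart
#'
#' The mechanical theory relating myocardial stiffness and wall/graft
#' thickness to the optimal gel point is not reproduced here; instead the
#' matcher performs a species-keyed lookup over the calibration's measured
#' design points (rat and pig by default), falling back to the design point
#' whose gel-point frequency is nearest (in log frequency) to the midpoint
#' of the requested heart-rate band when the species is not in the table.
#' Supplying `candidates` overrides the table: the candidate whose predicted
#' frequency is log-nearest to the band midpoint is chosen.
#'
#' @param heart A [heart_spec()].
#' @inheritParams predict_gel_point
#' @param candidates Optional data frame of candidate formulations
#'   (columns `gtn_wt_percent`, `fpba_fraction`).
#' @return A one-row tibble of class `design_result` with columns `species`,
#'   `gtn_wt_percent`, `fpba_fraction`, `f_gp_hz`, `g_gp_pa`,
#'   `target_modulus_pa` and `within_band` (whether the predicted frequency
#'   falls inside `rate_band_hz`).
#' @section Errors:
#' A band that does not intersect the calibrated frequency range signals
#' `gelstrain_unachievable_frequency`; a target modulus outside the
#' advertised tunable range signals `gelstrain_unachievable_modulus`.
#' @examples
#' match_formulation(heart_spec("rat", 5000, 2, 0.3, c(3.5, 4.5)))
#' @export
match_formulation <- function(heart, calibration = default_calibration(),
                              candidates = NULL) {
  if (!inherits(heart, "heart_spec")) {
    abort_domain("`heart` must be a `heart_spec`.")
  }
  validate_calibration(calibration)
  fk <- calibration$frequency_knots
  f_range <- range(fk$f_gp_hz)
  band <- heart$rate_band_hz
  if (band[2] < f_range[1] || band[1] > f_range[2]) {
    abort_gelstrain(
      sprintf(
        "heart-rate band [%g, %g] Hz is outside the achievable gel-point range [%g, %g] Hz.",
        band[1], band[2], f_range[1], f_range[2]),
      "gelstrain_unachievable_frequency")
  }
  midpoint <- exp(mean(log(band)))

  if (!is.null(candidates)) {
    check_columns(candidates, c("gtn_wt_percent", "fpba_fraction"),
                  "`candidates`")
    pred <- predict_gel_point(candidates, calibration)
    pick <- pred[which.min(abs(log(pred$f_gp_hz) - log(midpoint))), ]
    target_modulus <- pick$g_gp_pa
  } else {
    dt <- calibration$design_table
    row <- dt[dt$species == heart$species, ]
    if (nrow(row) == 0) {
      design_f <- pred_design_freq(dt, calibration)
      row <- dt[which.min(abs(log(design_f) - log(midpoint))), ]
    }
    pick <- predict_gel_point(row[, c("gtn_wt_percent", "fpba_fraction")],
                              calibration)
    target_modulus <- row$target_modulus_pa
  }

  mod_range <- calibration$modulus_range_pa
  if (target_modulus < mod_range[1] || target_modulus > mod_range[2]) {
    abort_gelstrain(
      sprintf(
        "target modulus %g Pa is outside the tunable range [%g, %g] Pa.",
        target_modulus, mod_range[1], mod_range[2]),
      "gelstrain_unachievable_modulus")
  }

  out <- tibble(
    species = heart$species,
    gtn_wt_percent = pick$gtn_wt_percent,
    fpba_fraction = pick$fpba_fraction,
    f_gp_hz = pick$f_gp_hz,
    g_gp_pa = pick$g_gp_pa,
    target_modulus_pa = target_modulus,
    within_band = pick$f_gp_hz >= band[1] & pick$f_gp_hz <= band[2])
  class(out) <- c("design_result", class(out))
  out
}

pred_design_freq <- function(design_table, calibration) {
  predict_gel_point(
    design_table[, c("gtn_wt_percent", "fpba_fraction")], calibration)$f_gp_hz
}
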