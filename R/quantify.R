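#' Apoptotic (TUNEL-positive) cell fraction
#'
#' \eqn{(\mathrm{TUNEL}^{+}\ \mathrm{nuclei} / \mathrm{total\ nuclei})
#' \times 100\%}, computed per sample.
#'
#' @param counts A data frame with integer columns `positives` and `total`
#'   (one row per sample; `0 <= positives <= total`, `total > 0`), e.g.
#'   read from a counts CSV with a `sample_id` column.  A pair of numeric
#'   vectors may be supplied instead as `tunel_fraction(positives, total)`.
#' @param total When `counts` is a numeric vector of positive counts, the
#'   matching vector of total counts.
#' @return The input tibble with a `tunel_pct` column appended (or a
#'   numeric vector of percentages for vector input).
#' @examples
#' tunel_fraction(25, 100)
#' @export
tunel_fraction <- function(counts, total = NULL) {
  if (is.data.frame(counts)) {
    check_columns(counts, c("positives", "total"), "`counts`")
    pos <- counts$positives
    tot <- counts$total
  } else {
    pos <- counts
    tot <- total
  }
  check_count_pair(pos, tot)
  pct <- pos / tot * 100
  if (is.data.frame(counts)) {
    out <- as_tibble(counts)
    out$tunel_pct <- pct
    out
  } else {
    pct
  }
}

check_count_pair <- function(positives, total) {
  check_numeric_vector(positives, "positives", nonnegative = TRUE)
  check_numeric_vector(total, "total", positive = TRUE)
  if (length(positives) != length(total)) {
    abort_domain("`positives` and `total` must have equal length.")
  }
  if (any(positives %% 1 != 0) || any(total %% 1 != 0)) {
    abort_domain("counts must be whole numbers.")
  }
  if (any(positives > total)) {
    abort_domain("`positives` cannot exceed `total`.")
  }
  invisible(NULL)
}

#' Infarct percentage of the ventricular wall
#'
#' \eqn{(\mathrm{fibrotic\ wall\ circumference} / \mathrm{total\ LV\ wall\
#' circumference}) \times 100\%}.
#'
#' @param fibrotic_circumference_mm Circumferential extent of the fibrotic
#'   (scarred) wall, mm; `0 <= fibrotic <= total`.
#' @param total_circumference_mm Total wall circumference, mm; > 0.
#' @return Infarct percentage(s) in \[0, 100\].
#' @examples
#' infarct_percentage(30, 120) # 25
#' @export
infarct_percentage <- function(fibrotic_circumference_mm,
                               total_circumference_mm) {
  check_numeric_vector(fibrotic_circumference_mm,
                       "fibrotic_circumference_mm", nonnegative = TRUE)
  check_numeric_vector(total_circumference_mm, "total_circumference_mm",
                       positive = TRUE)
  if (any(fibrotic_circumference_mm > total_circumference_mm)) {
    abort_domain("fibrotic circumference cannot exceed the total.")
  }
  fibrotic_circumference_mm / total_circumference_mm * 100
}

#' Minimum ventricular wall thickness from nested contours
#'
#' The minimum, over the (resampled) epicardial vertices, of the distance
#' from the vertex to the endocardial polyline.  Vertex-to-polyline distance
#' is used rather than a ray construction because it stays well defined for
#' non-convex walls; both contours are resampled to 360 arc-length points
#' before the minimum is taken.
#'
#' @param geometry Either a data frame with columns `x_mm`, `y_mm` and
#'   `surface` (values `"endo"` and `"epi"`, each an ordered closed
#'   contour; a `point_index` column, if present, sets the ordering), or a
#'   list with elements `endo` and `epi` holding the two contours.
#' @return Minimum wall thickness, mm.
#' @section Errors:
#' Contours that cross (the epicardial polygon does not strictly contain
#' the endocardial one) signal `gelstrain_geometry_error`.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 181)[-181]
#' geom <- rbind(
#'   data.frame(x_mm = 3 * cos(theta), y_mm = 3 * sin(theta),
#'              surface = "endo"),
#'   data.frame(x_mm = 5 * cos(theta), y_mm = 5 * sin(theta),
#'              surface = "epi"))
#' min_wall_thickness(geom) # 2
#' @export
min_wall_thickness <- function(geometry) {
  if (is.data.frame(geometry)) {
    check_columns(geometry, c("x_mm", "y_mm", "surface"), "`geometry`")
    pick <- function(s) {
      sub <- geometry[geometry$surface == s, ]
      if ("point_index" %in% names(sub)) sub <- sub[order(sub$point_index), ]
      sub
    }
    endo <- pick("endo")
    epi <- pick("epi")
  } else if (is.list(geometry) && all(c("endo", "epi") %in% names(geometry))) {
    endo <- geometry$endo
    epi <- geometry$epi
  } else {
    abort_domain(
      "`geometry` must supply `endo` and `epi` contours (see ?min_wall_thickness).")
  }
  endo <- resample_ring(ensure_ccw(as_contour_matrix(endo)),
                        CONTOUR_RESAMPLE_POINTS)
  epi <- resample_ring(ensure_ccw(as_contour_matrix(epi)),
                       CONTOUR_RESAMPLE_POINTS)

  endo_inside <- vapply(seq_len(nrow(endo)),
                        function(i) point_in_ring(endo[i, ], epi),
                        logical(1))
  epi_inside <- vapply(seq_len(nrow(epi)),
                       function(i) point_in_ring(epi[i, ], endo),
                       logical(1))
  if (!all(endo_inside) || any(epi_inside)) {
    abort_gelstrain(
      "epicardial contour must strictly contain the endocardial contour.",
      "gelstrain_geometry_error")
  }
  min(dist_points_to_ring(epi, endo))
}
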