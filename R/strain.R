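#' Define the angular segmentation of the short-axis wall
#'
#' The wall is subdivided into `n_segments` equal angular sectors about a
#' centroid, refining the classic 6-segment short-axis scheme (so
#' `n_segments` must be divisible by 6; the standard choice 24 splits each
#' of the 6 segments into 4).  Segments are Eulerian angular bins: the rays
#' are fixed in space about the reference-frame centroid rather than
#' tracking material points.  Segment 0 starts at `reference_angle`, angles
#' increase counterclockwise, and boundary `k` sits between segments `k`
#' and `k + 1` (mod `n_segments`); all indices are 0-based.
#'
#' @param n_segments Number of segments; divisible by 6 (default 24).
#' @param reference_angle Angle of the first sector boundary, radians
#'   (default 0).
#' @param centroid Optional fixed centroid `c(x_mm, y_mm)`; when `NULL`
#'   (default) [analyze_cine()] uses the area centroid of the
#'   end-diastolic contour.
#' @return A list of class `segmentation_scheme`.
#' @examples
#' segmentation_scheme()
#' @export
segmentation_scheme <- function(n_segments = 24, reference_angle = 0,
                                centroid = NULL) {
  check_number(n_segments, "n_segments", positive = TRUE)
  n_segments <- as.integer(n_segments)
  if (n_segments %% 6L != 0L) {
    abort_domain("`n_segments` must be divisible by 6.")
  }
  check_number(reference_angle, "reference_angle")
  if (!is.null(centroid)) {
    check_numeric_vector(centroid, "centroid", min_length = 2L)
    centroid <- centroid[1:2]
  }
  structure(list(n_segments = n_segments, reference_angle = reference_angle,
                 centroid = centroid),
            class = "segmentation_scheme")
}

# Number of arc-length resampling points applied to every contour before
# sector cutting; stabilizes the ray-intersection geometry.
CONTOUR_RESAMPLE_POINTS <- 360L

# ---- cine assembly ---------------------------------------------------------

# Split a cine table into per-frame analysis contours (mid-wall line when
# endocardial + epicardial contours are both present, else the single
# supplied contour).  Returns list(frame_index, time_s, contours = list of
# resampled CCW matrices).
cine_contours <- function(cine) {
  check_columns(cine, c("frame_index", "time_s", "point_index", "x_mm",
                        "y_mm"), "`cine`")
  has_surface <- "surface" %in% names(cine)
  frames <- sort(unique(cine$frame_index))
  if (length(frames) < 2) abort_data("a cine needs at least 2 frames.")
  times <- vapply(frames, function(f) {
    tt <- unique(cine$time_s[cine$frame_index == f])
    if (length(tt) != 1) abort_data("each frame must have a single time_s.")
    tt
  }, numeric(1))
  check_strictly_increasing(times, "time_s")

  contours <- lapply(frames, function(f) {
    rows <- cine[cine$frame_index == f, ]
    build_one <- function(sub) {
      sub <- sub[order(sub$point_index), ]
      if (nrow(sub) < 24) {
        abort_data(sprintf("frame %s has fewer than 24 contour points.", f))
      }
      ensure_ccw(as_contour_matrix(sub))
    }
    if (has_surface && all(c("endo", "epi") %in% rows$surface)) {
      endo <- build_one(rows[rows$surface == "endo", ])
      epi <- build_one(rows[rows$surface == "epi", ])
      centre <- (polygon_centroid(endo) + polygon_centroid(epi)) / 2
      endo_r <- resample_ring(align_ring_start(endo, centre),
                              CONTOUR_RESAMPLE_POINTS)
      epi_r <- resample_ring(align_ring_start(epi, centre),
                             CONTOUR_RESAMPLE_POINTS)
      (endo_r + epi_r) / 2
    } else {
      resample_ring(build_one(rows), CONTOUR_RESAMPLE_POINTS)
    }
  })
  list(frame_index = frames, time_s = times, contours = contours)
}

#' Locate the end-diastolic (largest-cavity) frame of a cine
#'
#' End-diastole is taken as the frame whose analysis contour encloses the
#' maximal polygon area (shoelace formula); ties resolve to the earliest
#' frame.  This frame serves as the reference state for circumferential
#' strain.
#'
#' @param cine A cine contour table: columns `frame_index`, `time_s`,
#'   `point_index`, `x_mm`, `y_mm` and optionally `surface`
#'   (`"endo"`/`"epi"`), as read by [read_cine_csv()] or generated by
#'   [generate_lv_cycle()].
#' @return The `frame_index` value of the end-diastolic frame.
#' @export
end_diastole_index <- function(cine) {
  cc <- cine_contours(cine)
  areas <- vapply(cc$contours, function(p) abs(signed_area(p)), numeric(1))
  cc$frame_index[which.max(areas)]
}

#' Arc length of each wall segment of a single contour
#'
#' Cuts the contour at the sector-boundary rays of `scheme` and returns the
#' polyline arc length between consecutive ray intersections.  Segment
#' lengths always sum to the contour perimeter (the cut is a partition).
#'
#' @param points A single closed contour: a data frame with `x_mm`, `y_mm`
#'   (ordered along the wall) or a two-column matrix.
#' @param scheme A [segmentation_scheme()]; its `centroid` defaults to the
#'   contour's own area centroid.
#' @return A tibble with columns `segment_index` (0-based) and `length_mm`.
#' @section Errors:
#' A centroid outside the contour signals `gelstrain_geometry_error`; a
#' contour that a boundary ray would cut more than once signals
#' `gelstrain_non_star_shaped`.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 241)[-241]
#' ring <- data.frame(x_mm = 5 * cos(theta), y_mm = 5 * sin(theta))
#' segment_arc_lengths(ring, segmentation_scheme()) # each ~ 2*pi*5/24
#' @export
segment_arc_lengths <- function(points, scheme = segmentation_scheme()) {
  pts <- ensure_ccw(as_contour_matrix(points))
  pts <- resample_ring(pts, CONTOUR_RESAMPLE_POINTS)
  centroid <- scheme$centroid %||% polygon_centroid(pts)
  lengths <- sector_lengths(pts, centroid, scheme$reference_angle,
                            scheme$n_segments)
  tibble(segment_index = seq_len(scheme$n_segments) - 1L,
         length_mm = lengths)
}

#' Circumferential strain of wall segments
#'
#' \eqn{\varepsilon_{cc} = (l_{current} - l_{reference}) / l_{reference}
#' \times 100\%} per segment, with the end-diastolic length as reference.
#' Negative values indicate contraction; positive values indicate passive
#' stretch of noncontractile (infarcted) wall.
#'
#' @param reference_lengths_mm,current_lengths_mm Equal-length numeric
#'   vectors of per-segment arc lengths, mm; reference lengths > 0.
#' @return Numeric vector of strains, percent.
#' @examples
#' circumferential_strain(10, 8) # -20
#' @export
circumferential_strain <- function(reference_lengths_mm,
                                   current_lengths_mm) {
  check_numeric_vector(reference_lengths_mm, "reference_lengths_mm",
                       positive = TRUE)
  check_numeric_vector(current_lengths_mm, "current_lengths_mm",
                       nonnegative = TRUE)
  if (length(reference_lengths_mm) != length(current_lengths_mm)) {
    abort_domain("reference and current lengths must have equal length.")
  }
  (current_lengths_mm - reference_lengths_mm) / reference_lengths_mm * 100
}

#' Strain differential between adjacent segments
#'
#' The circular adjacent-segment strain differential
#' \eqn{\Delta\varepsilon_{cc}[k] = |\varepsilon_{cc}[k] -
#' \varepsilon_{cc}[(k+1) \bmod n]|}, a proxy for the magnitude of the wall
#' strain gradient; it peaks at the border between noncontractile scar and
#' contracting myocardium.
#'
#' @param strains_pct Numeric vector of per-segment strains (percent),
#'   length >= 2.
#' @return Numeric vector of length `length(strains_pct)`; element `k`
#'   (0-based boundary index `k - 1`) is the differential across the
#'   boundary between segments `k - 1` and `k %% n`.
#' @examples
#' strain_differential(c(-20, -20, 0, 0))
#' @export
strain_differential <- function(strains_pct) {
  check_numeric_vector(strains_pct, "strains_pct", min_length = 2L)
  abs(strains_pct - c(strains_pct[-1], strains_pct[1]))
}

#' Maximum peak strain differential over a cardiac cycle
#'
#' The maximum over frames of the maximum over boundaries of
#' \eqn{\Delta\varepsilon_{cc}}: a single scalar summarizing the worst
#' strain gradient the wall experiences during the cycle.
#'
#' @param map A `strain_map` from [analyze_cine()], or its `differentials`
#'   tibble.
#' @return The maximum \eqn{\Delta\varepsilon_{cc}}, percent.
#' @export
max_peak_strain_differential <- function(map) {
  diffs <- if (inherits(map, "strain_map")) map$differentials else map
  check_columns(diffs, "delta_epsilon_cc_pct", "`map`")
  if (nrow(diffs) == 0) abort_domain("strain map has no boundary values.")
  max(diffs$delta_epsilon_cc_pct)
}

#' Mean strain within labelled wall zones
#'
#' @param strains_pct Numeric vector of per-segment strains, percent.
#' @param zones Character (or factor) vector of zone labels -- conventionally
#'   `"infarct"`, `"border"`, `"remote"` -- one per segment.
#' @return A tibble with columns `zone`, `mean_strain_pct` and `n_segments`,
#'   one row per label present.
#' @examples
#' zone_mean_strain(c(0, 0, -20, -20), c("infarct", "infarct", "remote",
#'                                       "remote"))
#' @export
zone_mean_strain <- function(strains_pct, zones) {
  check_numeric_vector(strains_pct, "strains_pct")
  zones <- as.character(zones)
  if (length(zones) != length(strains_pct) || anyNA(zones)) {
    abort_domain("`zones` must label every segment.")
  }
  tibble(zone = zones, strain = strains_pct) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(mean_strain_pct = mean(.data$strain),
                     n_segments = dplyr::n(), .groups = "drop")
}

#' Segmental strain analysis of a cine contour sequence
#'
#' The full wall-strain pipeline: the end-diastolic (maximal-area) frame is
#' taken as reference; every frame is cut into the scheme's angular sectors
#' about the reference-frame centroid (fixed rays, so the bins are
#' comparable across frames); per-segment circumferential strain is computed
#' against the reference lengths and the adjacent-segment differential
#' against each boundary.
#'
#' @inheritParams end_diastole_index
#' @param scheme A [segmentation_scheme()].
#' @return An object of class `strain_map`: a list with
#'   `reference_frame_index` (end-diastole), `end_systole_index`
#'   (minimal-area frame, for convenience), `centroid`, `scheme`,
#'   `lengths` (tibble: `frame_index`, `time_s`, `segment_index`,
#'   `length_mm`), `strains` (adds `epsilon_cc_pct`) and `differentials`
#'   (tibble: `frame_index`, `time_s`, `boundary_index`,
#'   `delta_epsilon_cc_pct`).  Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' phantom <- generate_lv_cycle(lv_phantom_spec(n_frames = 8, seed = 1))
#' sm <- analyze_cine(phantom$cine)
#' glance(sm)
#' @export
analyze_cine <- function(cine, scheme = segmentation_scheme()) {
  if (!inherits(scheme, "segmentation_scheme")) {
    abort_domain("`scheme` must be a `segmentation_scheme`.")
  }
  cc <- cine_contours(cine)
  areas <- vapply(cc$contours, function(p) abs(signed_area(p)), numeric(1))
  ref_pos <- which.max(areas)
  centroid <- scheme$centroid %||% polygon_centroid(cc$contours[[ref_pos]])
  n <- scheme$n_segments

  lengths <- dplyr::bind_rows(lapply(seq_along(cc$contours), function(i) {
    tibble(frame_index = cc$frame_index[i], time_s = cc$time_s[i],
           segment_index = seq_len(n) - 1L,
           length_mm = sector_lengths(cc$contours[[i]], centroid,
                                      scheme$reference_angle, n))
  }))
  ref_lengths <- lengths$length_mm[lengths$frame_index ==
                                     cc$frame_index[ref_pos]]
  strains <- lengths |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::mutate(epsilon_cc_pct =
                    circumferential_strain(ref_lengths, .data$length_mm)) |>
    dplyr::ungroup()
  differentials <- strains |>
    dplyr::group_by(.data$frame_index, .data$time_s) |>
    dplyr::reframe(
      boundary_index = seq_len(n) - 1L,
      delta_epsilon_cc_pct = strain_differential(.data$epsilon_cc_pct))

  structure(
    list(reference_frame_index = cc$frame_index[ref_pos],
         end_systole_index = cc$frame_index[which.min(areas)],
         centroid = centroid,
         scheme = scheme,
         lengths = lengths[, c("frame_index", "time_s", "segment_index",
                               "length_mm")],
         strains = strains,
         differentials = differentials,
         n_frames = length(cc$frame_index)),
    class = "strain_map")
}

#' @export
print.strain_map <- function(x, ...) {
  cat(sprintf(
    "Strain map: %d frames x %d segments (reference frame %s, end-systole %s)\n",
    x$n_frames, x$scheme$n_segments, x$reference_frame_index,
    x$end_systole_index))
  cat(sprintf("max peak strain differential: %.3f %%\n",
              max_peak_strain_differential(x)))
  invisible(x)
}

#' Tidiers for strain maps
#'
#' `tidy()` returns the per-frame per-segment table (strain joined with the
#' boundary differential whose index equals the segment index); `glance()`
#' a one-row summary.
#'
#' @param x A `strain_map` from [analyze_cine()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy strain_map
#' @export
tidy.strain_map <- function(x, ...) {
  dplyr::left_join(
    x$strains,
    x$differentials[, c("frame_index", "boundary_index",
                        "delta_epsilon_cc_pct")],
    by = c("frame_index", "segment_index" = "boundary_index"))
}

#' @rdname tidy.strain_map
#' @method glance strain_map
#' @export
glance.strain_map <- function(x, ...) {
  es <- x$strains[x$strains$frame_index == x$end_systole_index, ]
  tibble(
    n_frames = x$n_frames,
    n_segments = x$scheme$n_segments,
    reference_frame_index = x$reference_frame_index,
    end_systole_index = x$end_systole_index,
    mean_systolic_strain_pct = mean(es$epsilon_cc_pct),
    min_systolic_strain_pct = min(es$epsilon_cc_pct),
    max_peak_strain_differential_pct = max_peak_strain_differential(x))
}
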