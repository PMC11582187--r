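# Planar polygon / polyline helpers for wall contours.
# Contours are n x 2 matrices of vertices (mm), implicitly closed (the last
# vertex connects back to the first) and stored counterclockwise.

as_contour_matrix <- function(points) {
  if (is.data.frame(points)) {
    check_columns(points, c("x_mm", "y_mm"), "contour")
    points <- cbind(points$x_mm, points$y_mm)
  }
  if (!is.matrix(points) || ncol(points) != 2 || nrow(points) < 3 ||
      anyNA(points) || any(!is.finite(points))) {
    abort_gelstrain("a contour needs >= 3 finite planar points.",
                    "gelstrain_geometry_error")
  }
  # drop an explicit closing vertex
  n <- nrow(points)
  if (all(abs(points[1, ] - points[n, ]) < 1e-12)) points <- points[-n, , drop = FALSE]
  points
}

signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(pts) {
  if (signed_area(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ring_perimeter <- function(pts) {
  d <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
  sum(sqrt(rowSums(d^2)))
}

# Even-odd ray-casting point-in-polygon test.
point_in_ring <- function(pt, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  (sum(cross) %% 2) == 1
}

# Resample a closed ring to k vertices equally spaced in arc length,
# starting at the first vertex.
resample_ring <- function(pts, k = 360L) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- total * (seq_len(k) - 1L) / k
  cbind(approx(s, closed[, 1], xout = target)$y,
        approx(s, closed[, 2], xout = target)$y)
}

# Rotate vertex order so the ring starts at the vertex whose angle about
# `centre` is closest to `angle` (used to pair endo/epi samples point-wise).
align_ring_start <- function(pts, centre, angle = 0) {
  ang <- atan2(pts[, 2] - centre[2], pts[, 1] - centre[1])
  rel <- (ang - angle) %% (2 * pi)
  i <- which.min(pmin(rel, 2 * pi - rel))
  if (i > 1) pts <- rbind(pts[i:nrow(pts), , drop = FALSE],
                          pts[seq_len(i - 1L), , drop = FALSE])
  pts
}

# Cut a CCW ring into n equal angular sectors about `centroid` (sector 0
# starts at `ref_angle`, angles increase counterclockwise) and return the
# polyline arc length inside each sector.  Edges whose angular span straddles
# a boundary ray are split at the exact line-ray intersection and every piece
# is assigned to the sector containing its midpoint, so the sector lengths
# always sum to the ring perimeter.  The ring must be star-shaped about the
# centroid up to sub-sector jitter: it must wind exactly once
# counterclockwise and its angular coordinate may never fall more than one
# sector width behind its running maximum (a deeper backtrack means a
# boundary ray cuts the wall more than once).
sector_lengths <- function(pts, centroid, ref_angle, n) {
  if (!point_in_ring(centroid, pts)) {
    abort_gelstrain("segmentation centroid lies outside the contour.",
                    "gelstrain_geometry_error")
  }
  m <- nrow(pts)
  w <- 2 * pi / n
  rel <- sweep(pts, 2, centroid)
  ang <- (atan2(rel[, 2], rel[, 1]) - ref_angle) %% (2 * pi)
  dang <- diff(c(ang, ang[1]))
  dang <- (dang + pi) %% (2 * pi) - pi         # principal increments
  if (abs(sum(dang) - 2 * pi) > 1e-6) {
    abort_gelstrain(
      "contour does not wind exactly once counterclockwise about the centroid.",
      "gelstrain_non_star_shaped")
  }
  u <- c(ang[1], ang[1] + cumsum(dang))        # unwrapped angle, length m + 1
  if (max(cummax(u) - u) > w) {
    abort_gelstrain(
      "contour is not star-shaped about the centroid: a sector ray would intersect it more than once.",
      "gelstrain_non_star_shaped")
  }
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  edge_vec <- nxt - pts
  edge_len <- sqrt(rowSums(edge_vec^2))

  u1 <- u[-(m + 1)]
  u2 <- u[-1]
  lo <- pmin(u1, u2)
  hi <- pmax(u1, u2)
  b_first <- floor(lo / w) + 1              # boundary rays strictly inside
  b_last <- ceiling(hi / w) - 1             # the edge's angular span
  crossing <- b_first <= b_last

  lengths <- numeric(n)
  mid_bin <- (floor((((u1 + u2) / 2) %% (2 * pi)) / w) %% n) + 1L
  simple_add <- tapply(edge_len[!crossing], mid_bin[!crossing], sum)
  lengths[as.integer(names(simple_add))] <- simple_add

  bin_of_point <- function(p) {
    a <- (atan2(p[2] - centroid[2], p[1] - centroid[1]) - ref_angle) %%
      (2 * pi)
    (floor(a / w) %% n) + 1L
  }
  for (e in which(crossing)) {
    a <- pts[e, ]; v <- edge_vec[e, ]
    ts <- vapply(b_first[e]:b_last[e], function(b) {
      th <- ref_angle + b * w
      dir <- c(cos(th), sin(th))
      denom <- dir[1] * v[2] - dir[2] * v[1]
      if (abs(denom) < 1e-300) return(NA_real_)
      (dir[1] * (centroid[2] - a[2]) - dir[2] * (centroid[1] - a[1])) / denom
    }, numeric(1))
    ts <- ts[!is.na(ts) & ts > 0 & ts < 1]
    cuts <- sort(unique(c(0, ts, 1)))
    for (j in seq_len(length(cuts) - 1L)) {
      t_mid <- (cuts[j] + cuts[j + 1L]) / 2
      bin <- bin_of_point(a + t_mid * v)
      lengths[bin] <- lengths[bin] + (cuts[j + 1L] - cuts[j]) * edge_len[e]
    }
  }
  lengths
}

# Minimum distance from each query point to a closed polyline.
dist_points_to_ring <- function(query, ring) {
  a <- ring
  b <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), .Machine$double.xmin)
  vapply(seq_len(nrow(query)), function(i) {
    p <- query[i, ]
    t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- a[, 1] + t * ab[, 1] - p[1]
    dy <- a[, 2] + t * ab[, 2] - p[2]
    sqrt(min(dx^2 + dy^2))
  }, numeric(1))
}
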