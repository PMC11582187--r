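test_that("end-diastole is the largest-area frame, earliest on ties", {
  cine <- make_cine_df(c(sqrt(10 / pi), sqrt(8 / pi)))  # areas 10 then 8
  expect_equal(end_diastole_index(cine), 0)
  cine_tie <- make_cine_df(c(2, 2, 1.8))
  expect_equal(end_diastole_index(cine_tie), 0)
  # sinusoidally beating phantom: generator frame 0 is end-diastole
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 10, seed = 5))
  expect_equal(end_diastole_index(out$cine), 0)
})

test_that("a circle splits into 24 equal arcs that sum to the perimeter", {
  ring <- make_ring_df(5)
  for (ref in c(0, 0.3)) {
    sl <- segment_arc_lengths(ring, segmentation_scheme(reference_angle = ref))
    expect_equal(sl$length_mm, rep(mean(sl$length_mm), 24), tolerance = 1e-9)
    resampled <- gelstrain:::resample_ring(
      gelstrain:::as_contour_matrix(ring), 360L)
    expect_equal(sum(sl$length_mm), gelstrain:::ring_perimeter(resampled),
                 tolerance = 1e-12)
  }
})

test_that("ellipse sector lengths match the bisection oracle", {
  theta <- seq(0, 2 * pi, length.out = 481)[-481]
  ellipse <- data.frame(x_mm = 4 * cos(theta), y_mm = 2 * sin(theta))
  sl <- segment_arc_lengths(ellipse)
  resampled <- gelstrain:::resample_ring(
    gelstrain:::as_contour_matrix(ellipse), 360L)
  centroid <- gelstrain:::polygon_centroid(resampled)
  want <- oracle_sector_lengths(resampled, centroid, 0, 24)
  expect_equal(sl$length_mm, want, tolerance = 1e-6)
  expect_equal(sum(sl$length_mm), gelstrain:::ring_perimeter(resampled),
               tolerance = 1e-12)
})

test_that("bad geometry raises typed errors", {
  ring <- make_ring_df(5)
  off_centre <- segmentation_scheme(centroid = c(20, 0))
  expect_error(segment_arc_lengths(ring, off_centre),
               class = "gelstrain_geometry_error")
  # L-shaped wall: a point in one arm sees the far arm over repeated angles
  lshape <- data.frame(
    x_mm = c(0, 3, 3, 1, 1, 0),
    y_mm = c(0, 0, 1, 1, 3, 3))
  expect_error(
    segment_arc_lengths(lshape, segmentation_scheme(centroid = c(2, 0.5))),
    class = "gelstrain_non_star_shaped")
})

test_that("circumferential strain applies the printed formula and sign convention", {
  expect_equal(circumferential_strain(10, 8), -20)
  expect_equal(circumferential_strain(10, 11), 10)
  expect_equal(circumferential_strain(c(10, 5), c(10, 5)), c(0, 0))
  expect_error(circumferential_strain(c(10, 0), c(8, 1)),
               class = "gelstrain_domain_error")
  expect_error(circumferential_strain(10, c(8, 9)),
               class = "gelstrain_domain_error")
})

test_that("strain differential is the circular adjacent difference", {
  expect_equal(strain_differential(rep(-15, 24)), rep(0, 24))
  s <- c(-20, -20, 0, 0, rep(0, 20))
  d <- strain_differential(s)
  expect_equal(d[2], 20)              # boundary between segments 1 and 2
  expect_equal(d[24], 20)             # wrap boundary between 23 and 0
  set.seed(9)
  r <- rnorm(24, -10, 8)
  expect_equal(strain_differential(r), oracle_adjacent_diff(r))
})

test_that("the peak differential is the exhaustive double-loop maximum", {
  zero_map <- tibble::tibble(delta_epsilon_cc_pct = rep(0, 48))
  expect_equal(max_peak_strain_differential(zero_map), 0)
  one <- tibble::tibble(delta_epsilon_cc_pct = c(rep(0, 23), 20))
  expect_equal(max_peak_strain_differential(one), 20)

  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 8,
                                           point_noise_sd_mm = 0.02,
                                           seed = 13))
  sm <- analyze_cine(out$cine)
  brute <- -Inf
  for (f in unique(sm$differentials$frame_index)) {
    sub <- sm$differentials[sm$differentials$frame_index == f, ]
    for (k in seq_len(nrow(sub))) brute <- max(brute,
                                               sub$delta_epsilon_cc_pct[k])
  }
  expect_equal(max_peak_strain_differential(sm), brute)
})

test_that("zone means are per-label averages", {
  expect_equal(zone_mean_strain(rep(-20, 4), rep("remote", 4))$mean_strain_pct,
               -20)
  zm <- zone_mean_strain(c(0, 0, -20, -20),
                         c("infarct", "infarct", "remote", "remote"))
  expect_equal(zm$mean_strain_pct[zm$zone == "infarct"], 0)
  expect_equal(zm$mean_strain_pct[zm$zone == "remote"], -20)
  set.seed(14)
  s <- rnorm(24)
  z <- sample(c("infarct", "border", "remote"), 24, replace = TRUE)
  zm <- zone_mean_strain(s, z)
  for (lab in unique(z)) {
    expect_equal(zm$mean_strain_pct[zm$zone == lab], mean(s[z == lab]))
  }
  expect_error(zone_mean_strain(s, z[-1]), class = "gelstrain_domain_error")
})

test_that("strain is invariant to rigid translation of every frame", {
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 8, seed = 3))
  sm0 <- analyze_cine(out$cine)
  shifted <- dplyr::mutate(out$cine, x_mm = x_mm + 7.3, y_mm = y_mm - 2.1)
  sm1 <- analyze_cine(shifted)
  expect_equal(sm1$strains$epsilon_cc_pct, sm0$strains$epsilon_cc_pct,
               tolerance = 1e-9)
})

test_that("jointly rotating contours and reference angle leaves strain unchanged", {
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 8, seed = 3))
  phi <- 0.7
  rotated <- dplyr::mutate(out$cine,
                           x0 = x_mm, y0 = y_mm,
                           x_mm = cos(phi) * x0 - sin(phi) * y0,
                           y_mm = sin(phi) * x0 + cos(phi) * y0)
  sm0 <- analyze_cine(out$cine)
  sm1 <- analyze_cine(rotated,
                      segmentation_scheme(reference_angle = phi))
  expect_equal(sm1$strains$epsilon_cc_pct, sm0$strains$epsilon_cc_pct,
               tolerance = 1e-9)
})

test_that("a uniformly scaled frame gives uniform strain and zero differential", {
  cine <- make_cine_df(c(4, 4 * 0.9))
  sm <- analyze_cine(cine)
  cur <- sm$strains[sm$strains$frame_index == 1, ]
  expect_equal(cur$epsilon_cc_pct, rep(-10, 24), tolerance = 1e-9)
  expect_true(all(sm$differentials$delta_epsilon_cc_pct < 1e-9))
})

test_that("the strongest differential sits at a true border on noiseless infarct cines", {
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 12,
                                           transition_width_deg = 0,
                                           seed = 8))
  sm <- analyze_cine(out$cine)
  expect_lte(argmax_border_dist(sm, out$truth), 1)
  expect_equal(sm$reference_frame_index, out$truth$end_diastole_frame)
  expect_equal(sm$end_systole_index, out$truth$end_systole_frame)
})

test_that("mid-wall analysis uses the endo/epi midpoint line", {
  # concentric circles: mid-wall radius is the mean of the two radii
  theta <- 2 * pi * (0:119) / 120
  one_frame <- function(f, t, r_endo, r_epi) {
    rbind(
      tibble::tibble(frame_index = f, time_s = t, point_index = 0:119,
                     x_mm = r_endo * cos(theta), y_mm = r_endo * sin(theta),
                     surface = "endo"),
      tibble::tibble(frame_index = f, time_s = t, point_index = 0:119,
                     x_mm = r_epi * cos(theta), y_mm = r_epi * sin(theta),
                     surface = "epi"))
  }
  cine <- rbind(one_frame(0, 0, 3, 5), one_frame(1, 1, 2.4, 4.6))
  sm <- analyze_cine(cine)
  # mid-wall radii 4 and 3.5 -> strain -12.5%
  cur <- sm$strains[sm$strains$frame_index == 1, ]
  expect_equal(cur$epsilon_cc_pct, rep(-12.5, 24), tolerance = 1e-6)
})

test_that("tidy and glance summarise the map", {
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 6, seed = 2))
  sm <- analyze_cine(out$cine)
  td <- tidy(sm)
  expect_equal(nrow(td), 6 * 24)
  expect_true(all(c("epsilon_cc_pct", "delta_epsilon_cc_pct") %in% names(td)))
  gl <- glance(sm)
  expect_equal(gl$n_frames, 6)
  expect_equal(gl$reference_frame_index, 0)
})
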