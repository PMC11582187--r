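test_that("noiseless sweeps are exactly analytic and seeded runs reproduce", {
  sp <- maxwell_spectrum(c(600, 400), c(1, 0.01))
  clean <- generate_sweep(sp, 0.1, 10, 25, noise_cv = 0, seed = 1)
  expect_equal(clean, complex_moduli(sp, clean$frequency_hz))
  a <- generate_sweep(sp, 0.1, 10, 25, noise_cv = 0.05, seed = 99)
  b <- generate_sweep(sp, 0.1, 10, 25, noise_cv = 0.05, seed = 99)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_sweep(sp, 0.1, 10, 25, noise_cv = 0.05, seed = 100)))
  expect_error(generate_sweep(sp, 0.1, 10, 25, noise_cv = -0.1),
               class = "gelstrain_domain_error")
})

test_that("sweep noise has the requested coefficient of variation", {
  sp <- maxwell_spectrum(1000, 0.2)
  vals <- vapply(seq_len(1000), function(s) {
    generate_sweep(sp, 0.5, 2, 3, noise_cv = 0.05, seed = s)$g_prime_pa[2]
  }, numeric(1))
  cv <- stats::sd(vals) / mean(vals)
  expect_lt(abs(cv - 0.05) / 0.05, 0.2)
})

test_that("relaxation curves start at G0 and support recovery at 1% noise", {
  sp <- maxwell_spectrum(c(800, 200), c(10, 0.5))
  clean <- generate_relaxation_curve(sp, 50, 200, noise_cv = 0, seed = 1)
  expect_equal(clean$modulus_pa[1], 1000)
  expect_identical(generate_relaxation_curve(sp, 50, 200, 0.01, seed = 5),
                   generate_relaxation_curve(sp, 50, 200, 0.01, seed = 5))
  fit <- fit_relaxation(
    generate_relaxation_curve(sp, 50, 2000, 0.01, seed = 17))
  expect_equal(fit$spectrum$tau_s, c(10, 0.5), tolerance = 0.05)
})

test_that("generators never disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_sweep(maxwell_spectrum(1000, 1), 0.1, 10, 10, 0.05, 7))
  invisible(generate_lv_cycle(lv_phantom_spec(n_frames = 4,
                                              point_noise_sd_mm = 0.01,
                                              seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("the uniform phantom recovers the healthy peak exactly", {
  out <- generate_lv_cycle(lv_phantom_spec(infarct_span_deg = 0,
                                           n_frames = 8))
  sm <- analyze_cine(out$cine)
  peak <- sm$strains[sm$strains$frame_index == out$truth$end_systole_frame, ]
  expect_equal(peak$epsilon_cc_pct, rep(-20, 24), tolerance = 1e-3 * 20)
  expect_true(all(sm$differentials$delta_epsilon_cc_pct < 1e-6))
  expect_equal(out$truth$per_segment_peak_strain_pct$peak_strain_pct,
               rep(-20, 24), tolerance = 1e-6)
  expect_length(out$truth$border_boundaries, 0)
})

test_that("sharp-edged infarcts put the argmax differential at a true border", {
  out <- generate_lv_cycle(lv_phantom_spec(n_frames = 12,
                                           transition_width_deg = 0,
                                           seed = 4))
  expect_equal(out$truth$border_boundaries, c(2, 8))  # edges at 45 and 135 deg
  sm <- analyze_cine(out$cine)
  expect_lte(argmax_border_dist(sm, out$truth), 1)
  # determinism of the point clouds
  out2 <- generate_lv_cycle(lv_phantom_spec(n_frames = 12,
                                            transition_width_deg = 0,
                                            seed = 4))
  expect_identical(out$cine, out2$cine)
})

test_that("analyze_cine on dense noiseless output recovers truth within 1% of the strain scale", {
  spec <- lv_phantom_spec(n_frames = 20, n_points = 720, seed = 3)
  out <- generate_lv_cycle(spec)
  sm <- analyze_cine(out$cine)
  peak <- sm$strains[sm$strains$frame_index == out$truth$end_systole_frame, ]
  err <- abs(peak$epsilon_cc_pct -
               out$truth$per_segment_peak_strain_pct$peak_strain_pct)
  expect_lt(max(err) / abs(spec$healthy_peak_strain_pct), 1e-2)
})

test_that("an over-wide infarct is rejected as ill-posed", {
  expect_error(lv_phantom_spec(infarct_span_deg = 350,
                               transition_width_deg = 20),
               class = "gelstrain_domain_error")
})

test_that("recovery error grows along a noise ladder for strain and rheology", {
  sigma_ladder <- c(0, 0.05, 0.15)
  strain_err <- vapply(sigma_ladder, function(sigma) {
    errs <- vapply(1:5, function(s) {
      out <- generate_lv_cycle(lv_phantom_spec(n_frames = 8,
                                               point_noise_sd_mm = sigma,
                                               seed = s))
      sm <- analyze_cine(out$cine)
      peak <- sm$strains[sm$strains$frame_index ==
                           out$truth$end_systole_frame, ]
      mean(abs(peak$epsilon_cc_pct -
                 out$truth$per_segment_peak_strain_pct$peak_strain_pct))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(strain_err) > 0))

  sp <- maxwell_spectrum(c(800, 200), c(10, 0.5))
  relax_err <- vapply(c(0, 0.01, 0.1), function(cv) {
    errs <- vapply(1:5, function(s) {
      fit <- fit_relaxation(
        generate_relaxation_curve(sp, 50, 500, noise_cv = cv, seed = s))
      mean(abs(fit$spectrum$tau_s - c(10, 0.5)) / c(10, 0.5))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(relax_err) > 0))
})
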