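test_that("default calibration carries the measured design knots", {
  cal <- default_calibration()
  fk <- cal$frequency_knots
  expect_equal(fk$f_gp_hz[fk$fpba_fraction == 1.0], 0.3)
  expect_equal(fk$f_gp_hz[fk$fpba_fraction == 0.0], 6.0)
  mk <- cal$modulus_knots
  expect_equal(mk$g_gp_pa[mk$gtn_wt_percent == 20], 2500)
  expect_equal(mk$g_gp_pa[mk$gtn_wt_percent == 15], 1300)
  # knot monotonicity (type invariant)
  expect_true(all(diff(fk$fpba_fraction) > 0) && all(diff(fk$f_gp_hz) < 0))
  expect_true(all(diff(mk$gtn_wt_percent) > 0) && all(diff(mk$g_gp_pa) > 0))
  expect_equal(cal$modulus_range_pa, c(500, 2500))
})

test_that("predicted gel points pass exactly through every knot", {
  cal <- default_calibration()
  fk <- cal$frequency_knots
  at_knots <- predict_gel_point(
    tibble::tibble(gtn_wt_percent = 15, fpba_fraction = fk$fpba_fraction),
    cal)
  expect_equal(at_knots$f_gp_hz, fk$f_gp_hz, tolerance = 1e-12)
  mk <- cal$modulus_knots
  at_mk <- predict_gel_point(
    tibble::tibble(gtn_wt_percent = mk$gtn_wt_percent, fpba_fraction = 0.5),
    cal)
  expect_equal(at_mk$g_gp_pa, mk$g_gp_pa, tolerance = 1e-12)
})

test_that("the two selected recipes reproduce their printed gel points", {
  rat <- predict_gel_point(formulation(15, 0.2))
  expect_equal(rat$f_gp_hz, 4)
  expect_equal(rat$g_gp_pa, 1300)
  pig <- predict_gel_point(formulation(20, 0.6))
  expect_equal(pig$f_gp_hz, 1.3)
  expect_equal(pig$g_gp_pa, 2500)
})

test_that("frequency falls with FPBA fraction, modulus rises with wt%, independently", {
  frac_grid <- seq(0, 1, length.out = 101)
  pred_f <- predict_gel_point(
    tibble::tibble(gtn_wt_percent = 17, fpba_fraction = frac_grid))
  expect_true(all(diff(pred_f$f_gp_hz) < 0))

  wt_grid <- seq(15, 20, length.out = 51)
  pred_m <- predict_gel_point(
    tibble::tibble(gtn_wt_percent = wt_grid, fpba_fraction = 0.3))
  expect_true(all(diff(pred_m$g_gp_pa) > 0))

  # independence of the two coordinates
  a <- predict_gel_point(formulation(15, 0.4))
  b <- predict_gel_point(formulation(20, 0.4))
  expect_equal(a$f_gp_hz, b$f_gp_hz)
  c1 <- predict_gel_point(formulation(17, 0.1))
  c2 <- predict_gel_point(formulation(17, 0.9))
  expect_equal(c1$g_gp_pa, c2$g_gp_pa)
})

test_that("outside the calibrated hull the estimate is clamped or refused", {
  expect_warning(
    out <- predict_gel_point(
      tibble::tibble(gtn_wt_percent = 25, fpba_fraction = 0.2)),
    class = "gelstrain_extrapolation_warning")
  expect_equal(out$g_gp_pa, 2500)  # clamped to the 20 wt% knot
  expect_error(
    predict_gel_point(tibble::tibble(gtn_wt_percent = 25,
                                     fpba_fraction = 0.2), strict = TRUE),
    class = "gelstrain_extrapolation_error")
})

test_that("EGCG loadings above the mechanics-neutral 5 mM warn", {
  expect_warning(formulation(15, 0.2, egcg_mM = 6),
                 class = "gelstrain_egcg_warning")
  expect_no_warning(formulation(15, 0.2, egcg_mM = 5))
})

test_that("pure-endpoint formulations collapse to single modes with the printed times", {
  m0 <- formulation_to_modes(formulation(15, 0))
  expect_equal(nrow(m0), 1)
  expect_equal(m0$tau_s, 1 / (2 * pi * 6.0), tolerance = 1e-12)
  m1 <- formulation_to_modes(formulation(15, 1))
  expect_equal(m1$tau_s, 1 / (2 * pi * 0.3), tolerance = 1e-12)
  # single-mode crossover modulus is G0/2, so G0 = 2 * predicted modulus
  expect_equal(total_modulus(m0),
               2 * predict_gel_point(formulation(15, 0))$g_gp_pa)
})

test_that("constructed spectra reproduce the predicted gel point through the crossover solver", {
  for (fm in list(formulation(15, 0.2), formulation(20, 0.6))) {
    want <- predict_gel_point(fm)
    modes <- formulation_to_modes(fm)
    sweep <- complex_moduli(modes, exp(seq(log(want$f_gp_hz / 30),
                                           log(want$f_gp_hz * 30),
                                           length.out = 4001)))
    got <- find_gel_point(sweep)
    expect_equal(got$f_gp_hz, want$f_gp_hz, tolerance = 1e-6)
    expect_equal(got$g_gp_pa, want$g_gp_pa, tolerance = 1e-6)
  }
})

test_that("50 random in-hull formulations round-trip through modes within 1e-4", {
  set.seed(77)
  for (rep in 1:50) {
    fm <- random_formulation()
    want <- predict_gel_point(fm)
    modes <- formulation_to_modes(fm)
    sweep <- complex_moduli(modes, exp(seq(log(want$f_gp_hz / 20),
                                           log(want$f_gp_hz * 20),
                                           length.out = 2501)))
    got <- find_gel_point(sweep)
    expect_equal(got$f_gp_hz, want$f_gp_hz, tolerance = 1e-4)
    expect_equal(got$g_gp_pa, want$g_gp_pa, tolerance = 1e-4)
  }
})

test_that("the matcher returns the printed species design points", {
  rat <- match_formulation(heart_spec("rat", 5000, 2, 0.3, c(3.5, 4.5)))
  expect_equal(rat$gtn_wt_percent, 15)
  expect_equal(rat$fpba_fraction, 0.2)
  expect_equal(rat$f_gp_hz, 4)
  expect_equal(rat$g_gp_pa, 1300)
  expect_true(rat$within_band)

  pig <- match_formulation(heart_spec("pig", 5000, 9, 1, c(1.0, 1.5)))
  expect_equal(pig$gtn_wt_percent, 20)
  expect_equal(pig$fpba_fraction, 0.6)
  expect_equal(pig$f_gp_hz, 1.3)
  expect_equal(pig$g_gp_pa, 2500)
  expect_true(pig$within_band)
})

test_that("unknown species fall back to the log-nearest design point", {
  # a human-like band near 1.2 Hz should pick the slow (porcine) recipe
  human <- match_formulation(heart_spec("human", 5000, 10, 1, c(0.8, 2.2)))
  expect_equal(human$fpba_fraction, 0.6)
})

test_that("unreachable targets raise typed errors", {
  expect_error(
    match_formulation(heart_spec("rat", 5000, 2, 0.3, c(9, 11))),
    class = "gelstrain_unachievable_frequency")
  cal <- default_calibration()
  cal$design_table$target_modulus_pa[1] <- 4000
  expect_error(
    match_formulation(heart_spec("rat", 5000, 2, 0.3, c(3.5, 4.5)), cal),
    class = "gelstrain_unachievable_modulus")
})

test_that("explicit candidate sets are screened by band midpoint", {
  cands <- tibble::tibble(gtn_wt_percent = c(15, 18, 20),
                          fpba_fraction = c(0.1, 0.5, 0.9))
  res <- match_formulation(heart_spec("rat", 5000, 2, 0.3, c(3.5, 4.5)),
                           candidates = cands)
  expect_equal(res$fpba_fraction, 0.1)  # highest-frequency candidate
})
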