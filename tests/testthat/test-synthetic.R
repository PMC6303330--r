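test_that("synthetic curves honour their analytic form", {
  id <- make_synthetic_curve("identity", sigma = 10)
  lk <- cal_curve_lookup(id, 13000)
  expect_equal(lk$mu, 13000)
  expect_equal(lk$sigma, 10)

  wg <- make_synthetic_curve("wiggly", sigma = 15, wiggle_amp = 50,
                             wiggle_period = 1000)
  dev <- wg$grid$mu - wg$grid$calbp
  expect_lt(max(abs(dev)) - 50, 1e-6)
  expect_gt(max(abs(dev[wg$grid$calbp >= 12000 &
                         wg$grid$calbp <= 13000])), 49.9)

  # a wiggle strong enough for age reversals is flagged, not rejected
  expect_warning(rev <- make_synthetic_curve("wiggly", wiggle_amp = 500,
                                             wiggle_period = 1000,
                                             sigma = 10),
                 "non-monotone")
  expect_true(isTRUE(attr(rev, "non_monotone")))

  expect_error(make_synthetic_curve("identity", sigma = 0), "positive")

  # deterministic: identical file on disk across runs
  f1 <- tempfile(); f2 <- tempfile()
  write_cal_curve(make_synthetic_curve("wiggly", sigma = 15), f1)
  write_cal_curve(make_synthetic_curve("wiggly", sigma = 15), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("population curves encode the demographic ground truth", {
  flat <- scenario("exponential", r = 0)
  pc <- population_curve(flat)
  expect_true(all(pc$values == 1))

  bust <- scenario("exponential_with_bust", r = 0,
                   bust = c(12900, 12000), bust_depth = 0.6, ramp = 50)
  pb <- population_curve(bust)
  plateau <- pb$values[pb$calbp <= 12850 & pb$calbp >= 12050]
  expect_equal(unique(plateau), 0.4)
  expect_true(all(pb$values[pb$calbp > 12900 | pb$calbp < 12000] == 1))
  # ramps are linear between the edge and the plateau
  expect_equal(pb$values[pb$calbp == 12875], 0.7)

  degen <- scenario("richards", richards = list(A = 2, K = 2, B = 1e-3,
                                                M = 5000, nu = 1))
  expect_equal(unique(population_curve(degen)$values), 2)

  expect_error(scenario("exponential_with_bust", bust = NULL), "interval")
  expect_error(scenario("exponential_with_bust", bust = c(12900, 12000),
                        bust_depth = 1.2), "0, 1")
})

test_that("scenario draws are reproducible and follow the target density", {
  cc <- exact_curve()
  sc <- scenario("exponential", r = 0, window = c(14001, 15000),
                 n_dates = 1000, seed = 12)
  ds <- draw_scenario_dates(sc, cc)
  expect_equal(nrow(ds), 1000)
  truth <- attr(ds, "truth")
  expect_equal(truth$kind, "exponential")
  # constant population: per-century counts within 3 sigma of 100
  cent <- table(cut(truth$theta, breaks = seq(14000.5, 15000.5, by = 100)))
  expect_true(all(abs(cent - 100) <= 3 * sqrt(1000 * 0.1 * 0.9)))

  ds2 <- draw_scenario_dates(sc, cc)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))

  # identical CSV on disk across runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dates_csv(ds, f1); write_dates_csv(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
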