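test_that("null simulation respects the null shape and the seed", {
  cc <- exact_curve()
  g <- seq(20000, 10000, by = -1)

  # point-mass null with negligible curve error: every date lands there
  pm <- list(calbp = g, values = as.numeric(g == 14000))
  ds <- simulate_dateset_under_null(pm, 25, cc, sigma_pool = 0.001, seed = 4)
  expect_equal(ds$c14_age, rep(14000, 25), tolerance = 1e-6)

  # uniform null: per-century draw counts within 3 sigma of multinomial
  g2 <- seq(15000, 14001, by = -1)
  unif <- list(calbp = g2, values = rep(1, 1000))
  ds2 <- simulate_dateset_under_null(unif, 10000, cc, sigma_pool = 0.001,
                                     seed = 8)
  cent <- table(cut(ds2$c14_age, breaks = seq(14000.5, 15000.5, by = 100)))
  expected <- 10000 / 10
  sdm <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(cent - expected) <= 3 * sdm))

  # byte-identical under a fixed seed
  a <- simulate_dateset_under_null(pm, 10, cc, sigma_pool = c(30, 60),
                                   seed = 123)
  b <- simulate_dateset_under_null(pm, 10, cc, sigma_pool = c(30, 60),
                                   seed = 123)
  expect_identical(a, b)

  expect_error(simulate_dateset_under_null(pm, 10, cc, numeric(0)),
               "non-empty")
  neg <- list(calbp = g, values = rep(-1, length(g)))
  expect_error(simulate_dateset_under_null(neg, 10, cc, 30), "non-negative")
})

test_that("model test validates arguments and is fully deterministic", {
  cc <- identity_curve(c(9500, 20500), sigma = 10)
  sc <- scenario("exponential", n_dates = 40, seed = 3)
  ds <- draw_scenario_dates(sc, cc)
  s <- build_spd(ds, cc)
  nul <- fit_exponential_null(s, breakpoint = 10010)
  expect_error(run_model_test(s, nul, cc, ds$sigma_lab, nsim = 0), "nsim")

  mc1 <- run_model_test(s, nul, cc, ds$sigma_lab, nsim = 20, seed = 5)
  mc2 <- run_model_test(s, nul, cc, ds$sigma_lab, nsim = 20, seed = 5)
  expect_identical(mc1$z_obs, mc2$z_obs)
  expect_identical(mc1$global_p, mc2$global_p)
  expect_identical(mc1$bust_intervals, mc2$bust_intervals)

  # envelope sanity: bounds ordered, p in (0, 1]
  ok <- !is.na(mc1$ci_low)
  expect_true(all(mc1$ci_low[ok] <= mc1$ci_high[ok]))
  expect_gt(mc1$global_p, 0)
  expect_lte(mc1$global_p, 1)
})

test_that("terminal bust onset is the oldest year of the youngest bust", {
  mk <- function(iv) {
    structure(list(bust_intervals = iv), class = "mc_test_result")
  }
  expect_equal(terminal_bust_onset(mk(data.frame(
    start_calbp = 12600, end_calbp = 12300))), 12600)
  expect_true(is.na(terminal_bust_onset(mk(data.frame(
    start_calbp = numeric(0), end_calbp = numeric(0))))))
  expect_equal(terminal_bust_onset(mk(data.frame(
    start_calbp = c(13100, 12500), end_calbp = c(13000, 11900)))), 12500)
})

test_that("flagged runs merge into maximal non-overlapping intervals", {
  sc <- scenario("exponential_with_bust", bust = c(12900, 12000),
                 n_dates = 150, seed = 21)
  cc <- identity_curve(c(9500, 20500), sigma = 10)
  ds <- draw_scenario_dates(sc, cc)
  s <- build_spd(ds, cc)
  nul <- fit_exponential_null(s, breakpoint = 10010)
  mc <- run_model_test(s, nul, cc, ds$sigma_lab, nsim = 50, seed = 9)
  iv <- rbind(mc$bust_intervals, mc$boom_intervals)
  if (nrow(iv) > 1) {
    iv <- iv[order(-iv$start_calbp), ]
    # oldest-first intervals must not overlap
    expect_true(all(iv$end_calbp[-nrow(iv)] > iv$start_calbp[-1]))
  }
  expect_true(all(iv$start_calbp >= iv$end_calbp))
  succeed()
})
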