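test_that("breakpoint is recovered on a noiseless change-point series", {
  s <- changepoint_series(bp_cal = 13000, r_pre = 8e-4, r_post = -2e-3)
  bp <- fit_breakpoint(s, search = c(11000, 15000))
  expect_true(bp$interior_optimum)
  expect_lt(abs(bp$breakpoint_year - 13000), 50)
  expect_equal(bp$slope_pre, 8e-4, tolerance = 0.05)
  expect_equal(bp$slope_post, -2e-3, tolerance = 0.05)
})

test_that("a single-slope exponential has no interior optimum", {
  s <- changepoint_series(bp_cal = 13000, r_pre = 6e-4, r_post = 6e-4)
  bp <- fit_breakpoint(s, search = c(11000, 15000))
  expect_false(bp$interior_optimum)
})

test_that("breakpoint search validates margins and degenerate input", {
  s <- changepoint_series()
  expect_error(fit_breakpoint(s, search = c(10100, 15000)), "500 years")
  s0 <- s; s0$values[] <- 0
  expect_error(fit_breakpoint(s0), "all zero")
})

test_that("exponential null recovers noiseless input and extrapolates
           linearly in log space", {
  s <- changepoint_series(bp_cal = 13000, r_pre = 5e-4, r_post = -1e-3)
  nul <- fit_exponential_null(s, breakpoint = 13000)
  expect_equal(nul$beta1, 5e-4, tolerance = 1e-6)
  sel <- s$calbp >= 13000
  expect_equal(nul$fitted[sel], s$values[sel], tolerance = 1e-6)
  # extrapolation: exactly linear in log space beyond the breakpoint
  f_at <- function(cal) nul$fitted[s$calbp == cal]
  expect_equal(log(f_at(12000)), log(f_at(13000)) + 1000 * nul$beta1,
               tolerance = 1e-10)
  expect_error(fit_exponential_null(s, breakpoint = 19995), "10 grid years")
  expect_error(fit_exponential_null(s, breakpoint = 13000, fit_from = 12000),
               "older")
})

test_that("exponential slope survives multiplicative series noise", {
  s <- changepoint_series(bp_cal = 13000, r_pre = 5e-4, r_post = -1e-3,
                          noise_sd_frac = 0.05, seed = 31)
  nul <- fit_exponential_null(s, breakpoint = 13000)
  expect_equal(nul$beta1, 5e-4, tolerance = 0.05)
})

test_that("exponential null equals the weighted-least-squares oracle", {
  # on noiseless model-true data the quasi-Poisson IRLS solution equals the
  # exact log-linear solution, computed here by ordinary lm on log(y)
  s <- changepoint_series(bp_cal = 14000, r_pre = 3e-4, r_post = 0)
  nul <- fit_exponential_null(s, breakpoint = 14000)
  sel <- s$calbp >= 14000
  t <- (max(s$calbp) - s$calbp)[sel]
  ols <- lm(log(s$values[sel]) ~ t)
  expect_equal(nul$beta0, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(nul$beta1, unname(coef(ols)[2]), tolerance = 1e-8)
})

test_that("Richards parameters are recovered from noiseless data", {
  calbp <- seq(20000, 10000, by = -1)
  t <- 20000 - calbp
  truth <- list(A = 0.01, K = 1, B = 1.2e-3, M = 4000, nu = 1)
  y <- with(truth, A + (K - A) / (1 + exp(-B * (t - M)))^(1 / nu))
  s <- structure(list(calbp = calbp, values = y, n_dates = NA_integer_,
                      smoothing = 0, window = c(10000, 20000),
                      label = "richards"), class = "spd_series")
  fit <- fit_logistic_null(s, breakpoint = 10000 + 10, starts = 25, seed = 5)
  expect_true(fit$converged)
  expect_equal(fit$K, truth$K, tolerance = 0.1)
  expect_true(all(fit$fitted >= min(y) - 1e-6 &
                    fit$fitted <= max(y) + 1e-6))
})

test_that("exponential-phase data push the Richards asymptote far above
           the series", {
  s <- changepoint_series(bp_cal = 10010, r_pre = 4e-4, r_post = 4e-4)
  fit <- fit_logistic_null(s, breakpoint = 10010, starts = 25, seed = 2)
  expect_gt(fit$K, 2 * max(s$values))
})

test_that("pinning the lower asymptote at zero keeps the curve nonnegative", {
  s <- changepoint_series(bp_cal = 13000, r_pre = 5e-4, r_post = -1e-3)
  fit <- fit_logistic_null(s, breakpoint = 13000, starts = 10, seed = 3,
                           A_fixed = 0)
  expect_equal(fit$A, 0)
  expect_true(all(fit$fitted >= 0))
})
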