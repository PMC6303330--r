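# Shared fixtures, built in code at test time.

# identity curve with near-zero curve error, for exact expectations
exact_curve <- function(window = c(9500, 20500)) {
  identity_curve(window, sigma = 1e-9)
}

# small toy curve on a 50-year window, used against brute-force oracles
toy_curve <- function() {
  identity_curve(c(11975, 12025), sigma = 1e-9)
}

# date table with known vetting structure: 10 rows, 2 lab-id duplicates,
# 1 anomalous, 1 geological context -> 6 retained by the anthropogenic rules
vetting_fixture <- function() {
  date_set(data.frame(
    lab_id = c("L1", "L2", "L3", "L1", "L4", "L5", "L6", "L2", "L7", "L8"),
    c14_age = seq(12000, 12900, by = 100),
    sigma_lab = rep(50, 10),
    context = c("archaeological", "archaeological", "geological",
                "archaeological", "archaeological", "archaeological",
                "archaeological", "archaeological", "archaeological",
                "archaeological"),
    anomalous = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  FALSE, FALSE)))
}

# single-date set helper
one_date <- function(age, sigma, id = "X-1") {
  date_set(data.frame(lab_id = id, c14_age = age, sigma_lab = sigma))
}

# noiseless piecewise-exponential SPD-like series for breakpoint tests:
# growth at r_pre until bp_cal, then r_post, on an annual grid.
changepoint_series <- function(window = c(10000, 20000), bp_cal = 13000,
                               r_pre = 8e-4, r_post = -2e-3,
                               noise_sd_frac = 0, seed = NULL) {
  calbp <- seq(window[2], window[1], by = -1)
  t <- calbp[1] - calbp
  tb <- calbp[1] - bp_cal
  logy <- r_pre * pmin(t, tb) + r_post * pmax(t - tb, 0)
  y <- exp(logy)
  if (noise_sd_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y * (1 + rnorm(length(y), 0, noise_sd_frac)), 1e-12)
  }
  structure(list(calbp = calbp, values = y, n_dates = NA_integer_,
                 smoothing = 0, window = sort(window), label = "synthetic"),
            class = "spd_series")
}
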