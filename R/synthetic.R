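# Synthetic-data generator: calibration curves, demographic scenarios and
# date sets with known ground truth, so calibration, SPD construction,
# breakpoint detection and the Monte-Carlo test can all be validated
# end-to-end without external downloads.

#' An identity calibration curve
#'
#' Convenience wrapper around [make_synthetic_curve()]: mu(theta) = theta
#' with constant curve error, handy for tests whose expectations are exact.
#'
#' @param window Cal BP interval to cover.
#' @param sigma Constant curve error (14C yr, > 0).
#' @return A [cal_curve].
#' @export
identity_curve <- function(window = c(9500, 20500), sigma = 10) {
  make_synthetic_curve("identity", window = window, sigma = sigma)
}

#' Generate a synthetic calibration curve
#'
#' `"identity"` maps each calendar year to itself; `"wiggly"` superimposes
#' a sinusoid, `mu(theta) = theta + wiggle_amp * sin(2 pi theta /
#' wiggle_period)`, emulating the centennial-scale structure of real
#' curves. The curve error is constant. Knots are annual, so generated and
#' file-round-tripped curves agree exactly. A wiggle strong enough to make
#' mu non-monotone (as real curves' reversals do) is permitted but flagged
#' with a warning and attribute `"non_monotone"`.
#'
#' @param kind `"identity"` or `"wiggly"`.
#' @param window Cal BP interval to cover.
#' @param sigma Constant 1-sigma curve error (> 0).
#' @param wiggle_amp,wiggle_period Sinusoid amplitude (14C yr) and period
#'   (yr) for `"wiggly"`.
#' @param name Curve label.
#' @return A [cal_curve].
#' @export
make_synthetic_curve <- function(kind = c("identity", "wiggly"),
                                 window = c(9500, 20500), sigma = 20,
                                 wiggle_amp = 50, wiggle_period = 1000,
                                 name = NULL) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  window <- sort(as.numeric(window))
  theta <- seq(window[2], window[1], by = -1)
  mu <- switch(kind,
               identity = theta,
               wiggly = theta + wiggle_amp * sin(2 * pi * theta /
                                                   wiggle_period))
  cc <- cal_curve(theta, mu, rep(sigma, length(theta)), cal_range = window,
                  name = if (is.null(name)) paste0("synthetic-", kind)
                         else name)
  if (any(diff(mu) >= 0)) {   # theta descending: monotone curve has diff < 0
    warning("synthetic curve is non-monotone in 14C age (reversals)",
            call. = FALSE)
    attr(cc, "non_monotone") <- TRUE
  }
  cc
}

#' Define a demographic scenario with known ground truth
#'
#' Three scenario kinds cover the structures the null-model test is asked
#' to detect: steady exponential growth, exponential growth with an
#' imposed multiplicative bust (depth fraction over a calendar interval,
#' with linear edge ramps), and a five-parameter Richards logistic curve.
#'
#' @param kind `"exponential"`, `"exponential_with_bust"` or `"richards"`.
#' @param window Cal BP interval of the scenario.
#' @param n_dates Number of dates a draw produces.
#' @param r Exponential growth rate per elapsed year (toward the present).
#' @param bust Cal BP interval `c(older, younger)` of the imposed bust
#'   (required for `"exponential_with_bust"`).
#' @param bust_depth Fractional depth in (0, 1); 0.6 means the population
#'   drops to 40% of its counterfactual level.
#' @param ramp Linear ramp width at each bust edge (yr, default 50),
#'   avoiding grid-artifact discontinuities.
#' @param richards Named list `A, K, B, M, nu` (M in elapsed years from the
#'   oldest window year) for `"richards"`.
#' @param sigma_pool Lab-error pool resampled onto simulated dates. The
#'   default, 30--100 14C yr, spans the precision typical of late-
#'   Pleistocene assays.
#' @param seed Integer seed; every draw from the scenario is reproducible.
#' @return Object of class `scenario`.
#' @export
scenario <- function(kind = c("exponential", "exponential_with_bust",
                              "richards"),
                     window = c(10000, 20000), n_dates = 100,
                     r = 3e-4, bust = NULL, bust_depth = 0.6, ramp = 50,
                     richards = list(A = 0, K = 1, B = 1e-3, M = 5000,
                                     nu = 1),
                     sigma_pool = c(30, 40, 50, 60, 80, 100), seed = 1) {
  kind <- match.arg(kind)
  window <- sort(as.numeric(window))
  if (n_dates < 1) stop("n_dates must be >= 1", call. = FALSE)
  if (kind == "exponential_with_bust") {
    if (is.null(bust) || length(bust) != 2)
      stop("a bust interval c(older, younger) is required", call. = FALSE)
    bust <- sort(as.numeric(bust), decreasing = TRUE)
    if (bust_depth <= 0 || bust_depth >= 1)
      stop("bust_depth must lie in (0, 1)", call. = FALSE)
    if (bust[1] > window[2] || bust[2] < window[1])
      stop("bust interval must lie inside the scenario window",
           call. = FALSE)
  }
  if (length(sigma_pool) == 0L)
    stop("sigma_pool must be non-empty", call. = FALSE)
  structure(list(kind = kind, window = window, n_dates = n_dates, r = r,
                 bust = bust, bust_depth = bust_depth, ramp = ramp,
                 richards = richards, sigma_pool = sigma_pool, seed = seed),
            class = "scenario")
}

#' Per-year relative population curve of a scenario
#'
#' @param sc A [scenario].
#' @return List with `calbp` (annual, oldest first) and `values` (relative
#'   population level; arbitrary scale).
#' @export
population_curve <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  calbp <- seq(sc$window[2], sc$window[1], by = -1)
  t <- calbp[1] - calbp
  vals <- switch(sc$kind,
    exponential = exp(sc$r * t),
    exponential_with_bust = exp(sc$r * t) *
      bust_factor(calbp, sc$bust, sc$bust_depth, sc$ramp),
    richards = with(sc$richards, richards_curve(t, A, K, B, M, nu)))
  list(calbp = calbp, values = vals)
}

# multiplicative bust factor: 1 outside [older, younger]; ramps linearly
# from 1 at each edge down to (1 - depth) over `ramp` years inside.
bust_factor <- function(calbp, bust, depth, ramp) {
  f <- rep(1, length(calbp))
  older <- bust[1]; younger <- bust[2]
  inside <- calbp <= older & calbp >= younger
  depth_at <- pmin(1,
                   pmin(older - calbp, calbp - younger) / max(ramp, 1e-9))
  f[inside] <- 1 - depth * depth_at[inside]
  f
}

#' Draw a date set from a scenario through a calibration curve
#'
#' Calendar years are drawn with probability proportional to the scenario's
#' population curve, back-calibrated through `curve` (14C age drawn within
#' the per-year curve error) and given lab errors resampled from the
#' scenario's `sigma_pool`. The scenario's ground truth (kind, growth rate,
#' bust interval/depth or Richards parameters) is attached as attribute
#' `"truth"` for recovery testing. Fully reproducible from the scenario
#' seed.
#'
#' @param sc A [scenario].
#' @param curve A [cal_curve] covering the scenario window.
#' @return A [date_set] with attribute `"truth"`.
#' @export
draw_scenario_dates <- function(sc, curve) {
  stopifnot(inherits(sc, "scenario"), inherits(curve, "cal_curve"))
  pc <- population_curve(sc)
  set.seed(sc$seed %% .Machine$integer.max)
  theta <- pc$calbp[sample.int(length(pc$calbp), sc$n_dates, replace = TRUE,
                               prob = pc$values)]
  sim <- back_calibrate_sample(theta, curve, sc$sigma_pool)
  ds <- date_set(data.frame(lab_id = sprintf("syn_%05d", seq_len(sc$n_dates)),
                            c14_age = sim$c14_age,
                            sigma_lab = sim$sigma_lab),
                 label = paste0("synthetic-", sc$kind),
                 provenance = "draw_scenario_dates")
  attr(ds, "truth") <- list(kind = sc$kind, r = sc$r, bust = sc$bust,
                            bust_depth = sc$bust_depth,
                            richards = sc$richards, window = sc$window,
                            seed = sc$seed, theta = theta)
  ds
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$kind, "(", x$window[2], "-", x$window[1], "cal BP,",
      x$n_dates, "dates, seed", x$seed, ")\n")
  if (x$kind == "exponential") cat("  r =", x$r, "per yr\n")
  if (x$kind == "exponential_with_bust")
    cat("  r =", x$r, "per yr; bust", x$bust[1], "-", x$bust[2],
        "cal BP, depth", x$bust_depth, ", ramp", x$ramp, "yr\n")
  if (x$kind == "richards")
    cat("  Richards:", paste(names(x$richards), unlist(x$richards),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}
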