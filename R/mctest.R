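# Monte-Carlo null-model significance test: simulate date sets under the
# fitted null, rebuild SPDs exactly as the observed one, standardise per
# year by the simulated ensemble, flag boom/bust runs against the envelope
# and compute a global p-value.

# Deterministic per-simulation seed derived from the master seed by a
# counter-based splitting rule (documented so runs are auditable).
split_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483629 + 7919 * as.double(i)) %%
               2147483629)
}

as_null_values <- function(null) {
  if (inherits(null, c("exp_null", "logistic_null"))) return(null_values(null))
  if (is.list(null) && !is.null(null$calbp) && !is.null(null$values))
    return(list(calbp = null$calbp, values = null$values))
  stop("null must be a fitted null model or a list(calbp, values)",
       call. = FALSE)
}

#' Simulate a date set under a demographic null model
#'
#' Draws `n` calendar years with probability proportional to the per-year
#' null values, passes each back through the calibration curve (a 14C age
#' drawn within the curve error for that year) and attaches lab errors
#' resampled with replacement from `sigma_pool`, so simulated dates have
#' error structure comparable to the observed ones.
#'
#' @param null A fitted null model (`exp_null`/`logistic_null`) or a
#'   `list(calbp, values)` of non-negative per-year expected values.
#' @param n Number of dates to draw (>= 1).
#' @param curve A [cal_curve].
#' @param sigma_pool Non-empty pool of lab errors.
#' @param seed Optional integer seed (set for reproducibility).
#' @return A synthetic [date_set] with lab ids `sim_00001, ...`.
#' @export
simulate_dateset_under_null <- function(null, n, curve, sigma_pool,
                                        seed = NULL) {
  nv <- as_null_values(null)
  if (length(sigma_pool) == 0L)
    stop("sigma_pool must be non-empty", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(nv$values < 0) || all(nv$values == 0))
    stop("null values must be non-negative and not all zero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  theta <- nv$calbp[sample.int(length(nv$calbp), n, replace = TRUE,
                               prob = nv$values)]
  sim <- back_calibrate_sample(theta, curve, sigma_pool)
  date_set(data.frame(lab_id = sprintf("sim_%05d", seq_len(n)),
                      c14_age = sim$c14_age, sigma_lab = sim$sigma_lab),
           label = "simulated", provenance = "simulate_dateset_under_null")
}

# Global exceedance statistic of each simulation measured exactly as the
# observed series is measured: against the ensemble of the OTHER
# simulations. The observed series is external to the ensemble whose mean,
# SD and quantiles it is compared against; unless each simulation is
# treated the same way, simulations are compared against an envelope they
# helped define, their statistics are deflated, and the global p-value is
# anti-conservative.
#
# Two leave-one-out corrections follow from the algebra. (1) Quantiles:
# the j-th order statistic of a row with its k-th ranked element removed
# is s[j + (j >= rank_k)], so per-simulation quantiles come from one sort
# per year. (2) Mean/SD: restandardising both simulation k and the
# reference quantile by the leave-one-out mean cancels in the difference
# (z_k * n/(n-1) - q - z_k/(n-1) = z_k - q), leaving only the SD ratio
# sd/sd_{-k} = sqrt((n-2) / (n-1 - z_k^2 n/(n-1))) as a per-year scale on
# the exceedance. With both corrections each simulation's statistic is the
# statistic it would receive as the observed series against the remaining
# ensemble, so simulated and observed statistics are exchangeable under
# the null.
loo_exceedance_stats <- function(Zr, alpha) {
  nsim <- ncol(Zr); nyr <- nrow(Zr)
  if (nyr == 0L) return(numeric(nsim))
  S <- t(apply(Zr, 1L, sort))
  R <- t(apply(Zr, 1L, rank, ties.method = "first"))
  m <- nsim - 1L
  qidx <- function(p) {
    h <- (m - 1) * p + 1
    list(lo = floor(h), fr = h - floor(h))
  }
  ql <- qidx(alpha / 2); qh <- qidx(1 - alpha / 2)
  rows <- seq_len(nyr)
  stats <- numeric(nsim)
  for (k in seq_len(nsim)) {
    r <- R[, k]
    loo_q <- function(qi) {
      j1 <- qi$lo + (qi$lo >= r)
      j2 <- pmin(qi$lo + 1L, m) + (pmin(qi$lo + 1L, m) >= r)
      (1 - qi$fr) * S[cbind(rows, j1)] + qi$fr * S[cbind(rows, j2)]
    }
    zk <- Zr[, k]
    sd_ratio <- sqrt((nsim - 2) /
                       pmax(nsim - 1 - zk^2 * nsim / (nsim - 1), 1e-12))
    stats[k] <- sum(sd_ratio * (pmax(zk - loo_q(qh), 0) +
                                  pmax(loo_q(ql) - zk, 0)))
  }
  stats
}

# maximal runs of TRUE in a flag vector over a descending cal BP grid;
# returns a data.frame(start_calbp [older], end_calbp [younger]).
flag_runs <- function(calbp, flag) {
  if (!any(flag)) return(data.frame(start_calbp = numeric(0),
                                    end_calbp = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_calbp = calbp[starts[keep]], end_calbp = calbp[ends[keep]])
}

#' Monte-Carlo test of an observed SPD against a null model
#'
#' Runs the full simulation test: (1) `nsim` date sets are simulated under
#' the null and rebuilt into SPDs exactly as the observed one (same curve,
#' window and smoothing); (2) per-year ensemble mean and SD are computed
#' from the simulated SPDs only; (3) observed and simulated SPDs are
#' standardised per year into Z-scores, which de-trends calibration-curve
#' artifacts shared by all series; (4) the envelope is the per-year
#' `alpha/2` and `1 - alpha/2` quantiles of the simulated Z-scores;
#' (5) years inside `reporting_window` with observed Z strictly above the
#' upper bound are booms, strictly below the lower bound busts, merged into
#' maximal intervals; (6) the global statistic is the summed standardised
#' exceedance area outside the envelope over the reporting window, and
#' `global_p = (1 + #\{sims >= observed\}) / (1 + nsim)`. Each simulation's
#' statistic is measured against the envelope of the *other* simulations
#' (leave-one-out quantiles) so that simulated and observed statistics are
#' exchangeable under the null; comparing simulations to an envelope they
#' helped define deflates their statistics and makes the global p
#' anti-conservative.
#'
#' Years whose simulated SD is zero are excluded from flagging and from the
#' statistic, and listed in `excluded_years`.
#'
#' @param obs Observed `spd_series`.
#' @param null Fitted null model sharing the observed grid.
#' @param curve The [cal_curve] used to build `obs`.
#' @param sigma_pool Lab-error pool (typically the observed `sigma_lab`).
#' @param nsim Number of simulations (>= 2; default 500).
#' @param alpha Envelope tail probability (default 0.05).
#' @param reporting_window Cal BP interval over which booms/busts are
#'   flagged (default 15.0--10.0 ka).
#' @param seed Master integer seed; per-simulation seeds are derived by a
#'   counter-based rule so runs are fully reproducible.
#' @param n Dates per simulation; defaults to the observed count.
#' @return Object of class `mc_test_result`; see fields in the source and
#'   [terminal_bust_onset()], [write_mc_result_json()].
#' @export
run_model_test <- function(obs, null, curve, sigma_pool, nsim = 500,
                           alpha = 0.05,
                           reporting_window = c(10000, 15000),
                           seed = 1, n = obs$n_dates) {
  stopifnot(inherits(obs, "spd_series"))
  if (nsim < 2) stop("nsim must be >= 2", call. = FALSE)
  nv <- as_null_values(null)
  if (length(nv$values) != length(obs$values) ||
      any(nv$calbp != obs$calbp))
    stop("observed SPD and null model must share the grid", call. = FALSE)
  reporting_window <- sort(as.numeric(reporting_window))
  ny <- length(obs$calbp)
  S <- matrix(0, nrow = ny, ncol = nsim)
  for (k in seq_len(nsim)) {
    ds <- simulate_dateset_under_null(nv, n, curve, sigma_pool,
                                      seed = split_seed(seed, k))
    S[, k] <- spd_from_vectors(ds$c14_age, ds$sigma_lab, curve,
                               window = obs$window,
                               smoothing = obs$smoothing)$values
  }
  mu <- rowMeans(S)
  sdv <- sqrt(pmax(rowSums((S - mu)^2) / (nsim - 1), 0))
  usable <- sdv > 0
  z_obs <- rep(NA_real_, ny)
  z_obs[usable] <- (obs$values[usable] - mu[usable]) / sdv[usable]
  Z <- (S[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
  qs <- apply(Z, 1L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci_low <- rep(NA_real_, ny); ci_high <- rep(NA_real_, ny)
  ci_low[usable] <- qs[1, ]; ci_high[usable] <- qs[2, ]

  rep_sel <- obs$calbp >= reporting_window[1] &
    obs$calbp <= reporting_window[2] & usable
  boom <- rep(FALSE, ny); bust <- rep(FALSE, ny)
  boom[rep_sel] <- z_obs[rep_sel] > ci_high[rep_sel]
  bust[rep_sel] <- z_obs[rep_sel] < ci_low[rep_sel]

  exceed <- function(z, lo, hi) pmax(z - hi, 0) + pmax(lo - z, 0)
  obs_stat <- sum(exceed(z_obs[rep_sel], ci_low[rep_sel], ci_high[rep_sel]))
  rep_u <- which(rep_sel)
  Zr <- Z[match(rep_u, which(usable)), , drop = FALSE]
  sim_stats <- loo_exceedance_stats(Zr, alpha)
  global_p <- (1 + sum(sim_stats >= obs_stat)) / (1 + nsim)

  structure(list(nsim = nsim, calbp = obs$calbp, z_obs = z_obs,
                 ci_low = ci_low, ci_high = ci_high,
                 boom_intervals = flag_runs(obs$calbp, boom),
                 bust_intervals = flag_runs(obs$calbp, bust),
                 global_p = global_p, obs_stat = obs_stat,
                 sim_stats = sim_stats, seed = seed, alpha = alpha,
                 reporting_window = reporting_window,
                 excluded_years = obs$calbp[!usable],
                 n = n, label = obs$label),
            class = "mc_test_result")
}

#' Onset year of the terminal (youngest) bust
#'
#' The reported "date of terminal bust" is the oldest year of the youngest
#' maximal bust interval inside the reporting window.
#'
#' @param result An `mc_test_result`.
#' @return A cal BP year, or `NA` when no bust was flagged.
#' @export
terminal_bust_onset <- function(result) {
  stopifnot(inherits(result, "mc_test_result"))
  b <- result$bust_intervals
  if (nrow(b) == 0L) return(NA_real_)
  b$start_calbp[which.min(b$end_calbp)]
}

#' Serialise a Monte-Carlo test result to JSON
#' @param result An `mc_test_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mc_result_json <- function(result, path) {
  stopifnot(inherits(result, "mc_test_result"))
  jsonlite::write_json(
    list(label = result$label, nsim = result$nsim, n = result$n,
         alpha = result$alpha, seed = result$seed,
         reporting_window = result$reporting_window,
         global_p = result$global_p,
         boom_intervals = result$boom_intervals,
         bust_intervals = result$bust_intervals,
         terminal_bust_onset = terminal_bust_onset(result)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Per-year table of a Monte-Carlo test result
#' @param result An `mc_test_result`.
#' @return Data frame (cal BP, z_obs, ci_low, ci_high, flag).
#' @export
mc_result_table <- function(result) {
  stopifnot(inherits(result, "mc_test_result"))
  flag <- rep("", length(result$calbp))
  mark <- function(iv, what) {
    for (i in seq_len(nrow(iv))) {
      sel <- result$calbp <= iv$start_calbp[i] &
        result$calbp >= iv$end_calbp[i]
      flag[sel] <<- what
    }
  }
  mark(result$boom_intervals, "boom")
  mark(result$bust_intervals, "bust")
  data.frame(calbp = result$calbp, z_obs = result$z_obs,
             ci_low = result$ci_low, ci_high = result$ci_high, flag = flag)
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat("Monte-Carlo null-model test:", x$label, "\n")
  cat("  nsim =", x$nsim, " n =", x$n, " alpha =", x$alpha,
      " seed =", x$seed, "\n")
  cat("  reporting window:", x$reporting_window[2], "-",
      x$reporting_window[1], "cal BP\n")
  cat("  global p =", format(x$global_p, digits = 4), "\n")
  fmt_iv <- function(iv) if (nrow(iv) == 0L) "none" else
    paste(sprintf("[%d, %d]", round(iv$start_calbp), round(iv$end_calbp)),
          collapse = ", ")
  cat("  booms:", fmt_iv(x$boom_intervals), "\n")
  cat("  busts:", fmt_iv(x$bust_intervals), "\n")
  tb <- terminal_bust_onset(x)
  if (!is.na(tb)) cat("  terminal bust onset:", tb, "cal BP\n")
  invisible(x)
}

#' Plot an SPD with its null model and Monte-Carlo envelope
#'
#' Base-graphics summary panel: observed Z-scores, the simulation envelope,
#' and boom/bust rugs along the axis.
#'
#' @param x An `mc_test_result`.
#' @param ... Passed to [plot()].
#' @export
plot.mc_test_result <- function(x, ...) {
  ok <- !is.na(x$z_obs)
  plot(x$calbp[ok], x$z_obs[ok], type = "l", xlim = rev(range(x$calbp)),
       xlab = "cal BP", ylab = "Z score", ...)
  graphics::lines(x$calbp[ok], x$ci_low[ok], col = "purple", lty = 2)
  graphics::lines(x$calbp[ok], x$ci_high[ok], col = "purple", lty = 2)
  rug_at <- function(iv, col) {
    for (i in seq_len(nrow(iv)))
      graphics::segments(iv$start_calbp[i], graphics::par("usr")[3],
                         iv$end_calbp[i], graphics::par("usr")[3],
                         col = col, lwd = 3)
  }
  rug_at(x$boom_intervals, "blue")
  rug_at(x$bust_intervals, "red")
  invisible(x)
}
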