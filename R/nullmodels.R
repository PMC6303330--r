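# Null demographic models: segmented breakpoint detection on the SPD, and
# the exponential / Richards-logistic growth models extrapolated past the
# breakpoint to give the "had the population never declined" expectation.
#
# All fitting uses elapsed time t = (oldest grid year - cal BP), i.e. years
# since the start of the analysis window, increasing toward the present;
# slopes are per elapsed calendar year. Conversions to cal BP are explicit.

elapsed_time <- function(spd) max(spd$calbp) - spd$calbp

# One segmented quasi-Poisson log-link fit with the hinge at t = tb.
# Point estimates equal Poisson IRLS estimates; dispersion affects none.
segmented_deviance <- function(t, y, tb) {
  X <- cbind(1, t, pmax(t - tb, 0))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::quasipoisson(link = "log")))
  list(deviance = fit$deviance, coef = fit$coefficients,
       converged = isTRUE(fit$converged))
}

#' Locate the growth-to-decline breakpoint of an SPD
#'
#' Fits paired log-link quasi-Poisson GLM segments joined at a candidate
#' breakpoint and profiles the candidate over the annual grid: a coarse
#' pass every `step` years inside `search`, then 1-year refinement within
#' `step` years of the coarse optimum. The breakpoint is the candidate
#' minimising total deviance.
#'
#' When the deviance profile is flat (a single-slope exponential series) or
#' the optimum sits on the search boundary, there is no interior optimum
#' and `interior_optimum` is `FALSE`; the returned year is then not a
#' meaningful change point.
#'
#' @param spd An `spd_series`, strictly positive somewhere.
#' @param search Cal BP interval to search; must leave at least 500 years
#'   of margin to each end of the SPD window. Default: the window inset by
#'   500 years.
#' @param step Coarse profiling step in years (default 10).
#' @return Object of class `breakpoint_fit`: list with `breakpoint_year`
#'   (cal BP), `slope_pre`, `slope_post` (log-scale growth per elapsed
#'   year; pre = older segment), `deviance`, `interior_optimum`, `search`.
#' @export
fit_breakpoint <- function(spd, search = NULL, step = 10) {
  stopifnot(inherits(spd, "spd_series"))
  y <- spd$values
  if (all(y <= 0)) stop("SPD is all zero in the window", call. = FALSE)
  gr <- range(spd$calbp)
  if (is.null(search)) search <- c(gr[1] + 500, gr[2] - 500)
  search <- sort(as.numeric(search))
  if (search[1] - gr[1] < 500 || gr[2] - search[2] < 500)
    stop("search interval must leave >= 500 years on each side of the ",
         "SPD window", call. = FALSE)
  t <- elapsed_time(spd)
  t_old <- max(spd$calbp)
  cand_cal <- spd$calbp[spd$calbp >= search[1] & spd$calbp <= search[2]]
  coarse <- cand_cal[(cand_cal - min(cand_cal)) %% step == 0]
  dev <- vapply(t_old - coarse, function(tb) segmented_deviance(t, y, tb)$deviance,
                numeric(1))
  if (all(!is.finite(dev))) stop("segmented fit failed at every candidate",
                                 call. = FALSE)
  best <- coarse[which.min(dev)]
  fine <- cand_cal[abs(cand_cal - best) <= step]
  dev_f <- vapply(t_old - fine, function(tb) segmented_deviance(t, y, tb)$deviance,
                  numeric(1))
  bp <- fine[which.min(dev_f)]
  fit <- segmented_deviance(t, y, t_old - bp)
  dev_all <- c(dev, dev_f)
  flat <- (max(dev_all) - min(dev_all)) <=
    (1e-10 + 1e-6 * max(abs(dev_all)))
  on_edge <- bp <= min(cand_cal) + step || bp >= max(cand_cal) - step
  structure(list(breakpoint_year = bp,
                 slope_pre = unname(fit$coef[2]),
                 slope_post = unname(fit$coef[2] + fit$coef[3]),
                 deviance = fit$deviance,
                 interior_optimum = !(flat || on_edge),
                 search = search),
            class = "breakpoint_fit")
}

#' Fit the exponential null model and extrapolate it over the grid
#'
#' A single log-link quasi-Poisson GLM is fitted to the SPD on the rising
#' segment `[fit_from, breakpoint]` (cal BP) and predicted over the entire
#' grid, giving the expected trend of the series had growth never slowed.
#'
#' @param spd An `spd_series`.
#' @param breakpoint Cal BP year ending the fit window (younger bound).
#' @param fit_from Cal BP year starting the fit window (older bound);
#'   default the oldest grid year.
#' @return Object of class `exp_null`: list with `beta0`, `beta1`
#'   (log-scale intercept/slope per elapsed year), `fitted` (full grid),
#'   `calbp`, `fit_window`, `deviance`.
#' @export
fit_exponential_null <- function(spd, breakpoint, fit_from = NULL) {
  stopifnot(inherits(spd, "spd_series"))
  if (is.null(fit_from)) fit_from <- max(spd$calbp)
  if (fit_from <= breakpoint)
    stop("fit_from must be older (larger cal BP) than the breakpoint",
         call. = FALSE)
  sel <- spd$calbp <= fit_from & spd$calbp >= breakpoint
  if (sum(sel) < 10)
    stop("fewer than 10 grid years in the fit window", call. = FALSE)
  t <- elapsed_time(spd)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, t[sel]), spd$values[sel],
                   family = stats::quasipoisson(link = "log")))
  b <- fit$coefficients
  structure(list(beta0 = unname(b[1]), beta1 = unname(b[2]),
                 fitted = exp(b[1] + b[2] * t),
                 calbp = spd$calbp,
                 fit_window = c(breakpoint, fit_from),
                 deviance = fit$deviance),
            class = "exp_null")
}

richards_curve <- function(t, A, K, B, M, nu) {
  A + (K - A) / (1 + exp(-B * (t - M)))^(1 / nu)
}

#' Fit a five-parameter Richards logistic null model
#'
#' The Richards curve `y(t) = A + (K - A) / (1 + exp(-B (t - M)))^(1/nu)`
#' (lower asymptote `A`, upper asymptote / carrying-capacity analogue `K`,
#' rate `B`, inflection `M` in elapsed years, asymmetry `nu`) is fitted to
#' the SPD on `[fit_from, breakpoint]` by maximum likelihood under Gaussian
#' errors with the residual scale profiled out (equivalently, least
#' squares), using seeded multi-start Nelder-Mead from data-driven initial
#' values. On a series that is still in its exponential phase the fitted
#' `K` typically lands far above the data, mirroring the behaviour of such
#' fits on pre-decline growth series. The fit is extrapolated over the
#' full grid.
#'
#' @inheritParams fit_exponential_null
#' @param starts Number of jittered starts (default 25).
#' @param seed Integer seed for the start jitter (default 1).
#' @param A_fixed Optionally pin the lower asymptote (e.g. `0`).
#' @return Object of class `logistic_null`: list with `A`, `K`, `B`, `M`
#'   (elapsed years), `M_calbp`, `nu`, `resid_sd`, `converged`, `fitted`,
#'   `calbp`, `fit_window`.
#' @export
fit_logistic_null <- function(spd, breakpoint, fit_from = NULL, starts = 25,
                              seed = 1, A_fixed = NULL) {
  stopifnot(inherits(spd, "spd_series"))
  if (is.null(fit_from)) fit_from <- max(spd$calbp)
  if (fit_from <= breakpoint)
    stop("fit_from must be older (larger cal BP) than the breakpoint",
         call. = FALSE)
  sel <- spd$calbp <= fit_from & spd$calbp >= breakpoint
  if (sum(sel) < 10)
    stop("fewer than 10 grid years in the fit window", call. = FALSE)
  t_all <- elapsed_time(spd)
  t <- t_all[sel]; y <- spd$values[sel]
  fix_A <- !is.null(A_fixed)

  # parameters optimised on an unconstrained scale:
  # p = (A, log(K - A), log B, M, log nu); A dropped when fixed.
  unpack <- function(p) {
    A <- if (fix_A) A_fixed else p[1]
    o <- if (fix_A) 0 else 1
    list(A = A, K = A + exp(p[o + 1]), B = exp(p[o + 2]), M = p[o + 3],
         nu = exp(p[o + 4]))
  }
  sse <- function(p) {
    q <- unpack(p)
    r <- y - richards_curve(t, q$A, q$K, q$B, q$M, q$nu)
    s <- sum(r * r)
    if (!is.finite(s)) 1e300 else s
  }
  ymax <- max(y); yspan <- diff(range(t))
  base_start <- c(if (!fix_A) min(y),
                  log(max(ymax - min(y), ymax, 1e-12)),
                  log(4 / yspan),
                  t[which.min(abs(y - (min(y) + ymax) / 2))],
                  0)
  set.seed(seed %% .Machine$integer.max)
  best <- NULL; any_conv <- FALSE
  for (s in seq_len(starts)) {
    p0 <- base_start
    if (s > 1) {
      jit <- stats::rnorm(length(p0), 0, c(if (!fix_A) 0.5 * ymax,
                                           1, 1, 0.25 * yspan, 0.7))
      p0 <- p0 + jit
    }
    res <- tryCatch(
      stats::optim(p0, sse, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all Richards starts failed; consider the exponential null instead",
         call. = FALSE)
  q <- unpack(best$par)
  structure(list(A = q$A, K = q$K, B = q$B, M = q$M,
                 M_calbp = max(spd$calbp) - q$M, nu = q$nu,
                 resid_sd = sqrt(best$value / length(y)),
                 converged = any_conv && best$convergence == 0,
                 fitted = richards_curve(t_all, q$A, q$K, q$B, q$M, q$nu),
                 calbp = spd$calbp,
                 fit_window = c(breakpoint, fit_from)),
            class = "logistic_null")
}

# Per-year expected values of any null model (shared accessor).
null_values <- function(null) {
  if (inherits(null, c("exp_null", "logistic_null")))
    return(list(calbp = null$calbp, values = null$fitted))
  stop("not a fitted null model", call. = FALSE)
}

#' Export a fitted null model as CSV (cal BP, expected value)
#' @param null An `exp_null` or `logistic_null`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_csv <- function(null, path) {
  nv <- null_values(null)
  utils::write.csv(data.frame(calbp = nv$calbp, expected = nv$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Breakpoint:", x$breakpoint_year, "cal BP",
      if (!x$interior_optimum) "(no interior optimum)", "\n")
  cat("  slopes (per elapsed yr): pre =", format(x$slope_pre, digits = 4),
      " post =", format(x$slope_post, digits = 4),
      " deviance =", format(x$deviance, digits = 6), "\n")
  invisible(x)
}

#' @export
print.exp_null <- function(x, ...) {
  cat("Exponential null: log(y) =", format(x$beta0, digits = 5), "+",
      format(x$beta1, digits = 5), "* t (elapsed yr)\n",
      " fit window:", x$fit_window[2], "-", x$fit_window[1], "cal BP\n")
  invisible(x)
}

#' @export
print.logistic_null <- function(x, ...) {
  cat("Richards logistic null (A =", format(x$A, digits = 4),
      ", K =", format(x$K, digits = 4), ", B =", format(x$B, digits = 4),
      ",\n  M =", round(x$M_calbp), "cal BP, nu =", format(x$nu, digits = 4),
      "); converged:", x$converged, "\n")
  invisible(x)
}
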