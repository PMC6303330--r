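#' Calibrate a radiocarbon measurement to a calendar-year density
#'
#' For each calendar year theta on the curve grid the likelihood of the
#' measurement is the normal density of `c14_age` at mean mu(theta) and
#' standard deviation sqrt(sigma_lab^2 + sigma_curve(theta)^2); the result
#' is normalised to a probability mass function over the grid. No tail
#' trimming is applied: the full grid is kept.
#'
#' @param c14_age Measured radiocarbon age (14C yr BP).
#' @param sigma_lab Laboratory 1-sigma error (14C yr, >= 0).
#' @param curve A [cal_curve].
#' @param window Optional cal BP interval restricting (and normalising over)
#'   a sub-window of the grid.
#' @param date_ref Identifier carried along with the density.
#' @return An object of class `cal_density`: list with `calbp` (annual grid,
#'   oldest first), `prob` (sums to 1) and `date_ref`.
#' @examples
#' cc <- identity_curve(c(11000, 13000))
#' d <- calibrate_date(12000, 50, cc)
#' sum(d$prob)
#' @export
calibrate_date <- function(c14_age, sigma_lab, curve, window = NULL,
                           date_ref = NA_character_) {
  stopifnot(inherits(curve, "cal_curve"))
  if (!is.finite(c14_age)) stop("c14_age must be finite", call. = FALSE)
  if (!is.finite(sigma_lab) || sigma_lab < 0)
    stop("sigma_lab must be >= 0", call. = FALSE)
  g <- curve_grid(curve, window)
  sd_tot <- sqrt(sigma_lab^2 + g$sigma^2)
  if (any(sd_tot == 0)) {
    hit <- sd_tot == 0 & g$mu == c14_age
    if (any(hit)) {
      prob <- as.numeric(hit) / sum(hit)
      return(structure(list(calbp = g$calbp, prob = prob, date_ref = date_ref),
                       class = "cal_density"))
    }
    if (all(sd_tot == 0))
      stop("degenerate density: sigma_lab = 0, zero curve error and no grid ",
           "year matches c14_age = ", c14_age, call. = FALSE)
  }
  dens <- numeric(nrow(g))
  ok <- sd_tot > 0
  dens[ok] <- stats::dnorm(c14_age, mean = g$mu[ok], sd = sd_tot[ok])
  tot <- sum(dens)
  if (!is.finite(tot) || tot <= 0)
    stop("date (", c14_age, " +/- ", sigma_lab,
         ") lies outside the support of the calibration curve", call. = FALSE)
  structure(list(calbp = g$calbp, prob = dens / tot, date_ref = date_ref),
            class = "cal_density")
}

# Matrix of normalised calibrated densities, one column per date, over the
# (possibly windowed) grid. Internal workhorse for SPD construction.
calibrate_matrix <- function(c14_age, sigma_lab, curve, window = NULL) {
  g <- curve_grid(curve, window)
  n <- length(c14_age)
  out <- matrix(0, nrow = nrow(g), ncol = n)
  sig2 <- g$sigma^2
  for (j in seq_len(n)) {
    sd_tot <- sqrt(sigma_lab[j]^2 + sig2)
    d <- stats::dnorm(c14_age[j], mean = g$mu, sd = sd_tot)
    tot <- sum(d)
    if (!is.finite(tot) || tot <= 0)
      stop("date ", j, " (", c14_age[j], " +/- ", sigma_lab[j],
           ") lies outside the calibration window", call. = FALSE)
    out[, j] <- d / tot
  }
  attr(out, "calbp") <- g$calbp
  out
}

#' Simulate the radiocarbon measurement of a known calendar year
#'
#' The reverse of calibration, used by the Monte-Carlo null-model test: a
#' calendar year is pushed back through the curve by drawing a 14C age from
#' Normal(mu(theta), sigma_curve(theta)) and attaching a lab error resampled
#' with replacement from an empirical pool. Vectorised over `theta`; driven
#' by R's global RNG (seed with [set.seed()] for reproducibility).
#'
#' @param theta Calendar years (cal BP) on the curve support.
#' @param curve A [cal_curve].
#' @param sigma_pool Non-empty numeric pool of lab errors to resample.
#' @return Data frame with columns `c14_age` and `sigma_lab`.
#' @export
back_calibrate_sample <- function(theta, curve, sigma_pool) {
  if (length(sigma_pool) == 0L)
    stop("sigma_pool must be non-empty", call. = FALSE)
  lk <- cal_curve_lookup(curve, theta)
  n <- length(theta)
  data.frame(
    c14_age = stats::rnorm(n, mean = lk$mu, sd = lk$sigma),
    sigma_lab = sigma_pool[sample.int(length(sigma_pool), n, replace = TRUE)])
}

#' Export a calibrated density as a two-column CSV
#'
#' @param dens A `cal_density`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cal_density <- function(dens, path) {
  stopifnot(inherits(dens, "cal_density"))
  utils::write.csv(data.frame(calbp = dens$calbp, prob = dens$prob),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cal_density <- function(x, ...) {
  m <- x$calbp[which.max(x$prob)]
  cat("Calibrated density", if (!is.na(x$date_ref)) paste0("[", x$date_ref, "]"),
      "\n  grid:", max(x$calbp), "-", min(x$calbp), "cal BP;",
      "modal year:", m, "cal BP\n")
  invisible(x)
}
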