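# SPD comparison statistics: rank correlation between two series and
# power-law taphonomic correction of an SPD.

# All permutations of 1..n as an (n! x n) integer matrix, built by
# inserting n into every position of each permutation of 1..(n-1).
all_permutations <- function(n) {
  if (n > 10L) stop("exact permutation enumeration limited to n <= 10",
                    call. = FALSE)
  p <- matrix(1L, 1L, 1L)
  for (m in 2L:max(2L, n)) {
    if (n == 1L) break
    r <- nrow(p)
    out <- matrix(0L, r * m, m)
    for (pos in seq_len(m)) {
      rows <- ((pos - 1L) * r + 1L):(pos * r)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <-
          p[, seq_len(pos - 1L), drop = FALSE]
      out[rows, pos] <- m
      if (pos < m) out[rows, (pos + 1L):m] <- p[, pos:(m - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}

spearman_rho <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("rank correlation undefined for a constant series", call. = FALSE)
  stats::cor(ra, rb)
}

#' Rank correlation between two SPDs over a calendar window
#'
#' Spearman's rho (average ranks, so ties are handled) on the per-year
#' values of the two series over the shared annual grid inside `window`.
#' The two-tailed p-value uses the t-distribution approximation
#' `t = rho sqrt((n-2)/(1-rho^2))`; for `n <= 10` an exact two-tailed
#' permutation p (all n! orderings) is available. Annual SPD samples are
#' strongly autocorrelated; no adjustment is applied, and `n_years` is
#' reported so readers can judge the effective sample size.
#'
#' @param a,b `spd_series` objects on a shared annual grid covering
#'   `window`.
#' @param window Cal BP interval (default 15.0--11.7 ka).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact permutation
#'   p-value; default `NULL` uses it automatically when `n <= 10`.
#' @return Object of class `correlation_result`: list with `rho`,
#'   `p_two_tailed`, `method`, `n_years`, `window`, `labels`.
#' @export
spearman_spd <- function(a, b, window = c(11700, 15000), exact = NULL) {
  stopifnot(inherits(a, "spd_series"), inherits(b, "spd_series"))
  window <- sort(as.numeric(window))
  sa <- window_series(a, window); sb <- window_series(b, window)
  if (length(sa$calbp) != length(sb$calbp) || any(sa$calbp != sb$calbp))
    stop("series do not share an annual grid over the window", call. = FALSE)
  x <- sa$values; y <- sb$values
  n <- length(x)
  if (n < 3) stop("window must contain at least 3 shared years", call. = FALSE)
  rho <- spearman_rho(x, y)
  use_exact <- if (is.null(exact)) n <= 10L else exact
  if (use_exact) {
    ra <- rank(x); rb <- rank(y)
    perms <- all_permutations(n)
    Rb <- matrix(rb[perms], nrow(perms), n)
    s <- as.vector(Rb %*% ra)
    # rho is affine in sum(ra * rb_perm), so compare on that scale
    mra <- mean(ra); mrb <- mean(rb)
    denom <- (n - 1) * stats::sd(ra) * stats::sd(rb)
    rho_all <- (s - n * mra * mrb) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, p)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_two_tailed = p, method = method,
                 n_years = n, window = window,
                 labels = c(a$label, b$label)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman rank correlation:", x$labels[1], "vs", x$labels[2], "\n")
  cat("  window:", x$window[2], "-", x$window[1], "cal BP (",
      x$n_years, "years )\n")
  cat("  rho =", format(x$rho, digits = 3), " two-tailed p =",
      format(x$p_two_tailed, digits = 3), "(", x$method, ")\n")
  cat("  note: annual samples are autocorrelated; n_years overstates the",
      "effective sample size\n")
  invisible(x)
}

#' Taphonomic survival-curve constants of Surovell and colleagues
#'
#' The widely used power-law description of taphonomic loss,
#' `s(t) = a (t + c)^b`: the expected surviving proportion of dateable
#' material of age `t` cal BP. These constants are configuration defaults,
#' not assertions; pass alternatives to [taphonomic_correct()].
#'
#' @return Named list with elements `a`, `b`, `c`.
#' @export
surovell_taphonomy <- function() {
  list(a = 5726442, b = -1.3925309, c = 2176.4)
}

#' Correct an SPD for taphonomic loss
#'
#' Divides each per-year value by the survival function
#' `s(t) = a (t + c)^b` (older material survives less, so older years are
#' up-weighted when `b < 0`) and renormalises so the corrected series keeps
#' the original total mass.
#'
#' @param spd An `spd_series`.
#' @param a,b,c Survival-curve constants; defaults from
#'   [surovell_taphonomy()].
#' @return The corrected `spd_series`.
#' @export
taphonomic_correct <- function(spd, a = surovell_taphonomy()$a,
                               b = surovell_taphonomy()$b,
                               c = surovell_taphonomy()$c) {
  stopifnot(inherits(spd, "spd_series"))
  s <- a * (spd$calbp + c)^b
  if (any(!is.finite(s)) || any(s <= 0))
    stop("survival function must be strictly positive on the grid",
         call. = FALSE)
  corrected <- spd$values / s
  tot0 <- sum(spd$values); tot1 <- sum(corrected)
  if (tot1 > 0) corrected <- corrected * (tot0 / tot1)
  out <- spd
  out$values <- corrected
  out$label <- paste0(spd$label, " [taphonomically corrected]")
  out
}
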