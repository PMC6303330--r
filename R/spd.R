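#' Centered moving average with shrinking edge windows
#'
#' The window is centered and symmetric: an averaging half-width `h` is
#' derived from `width` (`h = floor(width / 2)`, so a 200-year request uses
#' an effective 201-year window). Near the series ends the half-width
#' shrinks symmetrically to the years available, which leaves constant
#' series unchanged everywhere and conserves total mass for any signal
#' whose support lies at least `h` years from the ends.
#'
#' @param x Numeric series on a regular (annual) grid.
#' @param width Window width in grid steps (years); `width <= 1` is a no-op.
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(x, width) {
  n <- length(x)
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  h <- floor(width / 2)
  if (h == 0L) return(x)
  if (2 * h + 1 > n)
    stop("smoothing window (", 2 * h + 1, ") exceeds series length (", n, ")",
         call. = FALSE)
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1)
}

#' Build a summed probability distribution (SPD)
#'
#' Each date is calibrated on the annual grid restricted to `window`, its
#' density normalised to unit mass, the densities summed, and the sum
#' smoothed with a centered moving average (default 200 years). Before
#' smoothing the series total equals the number of dates.
#'
#' @param ds A non-empty, vetted [date_set].
#' @param curve A [cal_curve] whose grid covers `window`.
#' @param window Cal BP interval of the analysis grid (default 10--20 ka).
#' @param smoothing Moving-average width in years (default 200; `0` or `1`
#'   disables smoothing).
#' @param label Series label.
#' @return An object of class `spd_series`: list with `calbp` (oldest
#'   first), `values`, `n_dates`, `smoothing`, `window`, `label`.
#' @examples
#' cc <- identity_curve(c(10000, 20000))
#' ds <- date_set(data.frame(lab_id = "X-1", c14_age = 15000, sigma_lab = 80))
#' s <- build_spd(ds, cc)
#' sum(s$values)  # ~ 1 date
#' @export
build_spd <- function(ds, curve, window = c(10000, 20000), smoothing = 200,
                      label = attr(ds, "label")) {
  stopifnot(inherits(ds, "date_set"), inherits(curve, "cal_curve"))
  if (nrow(ds) == 0L) stop("empty date set", call. = FALSE)
  dens <- calibrate_matrix(ds$c14_age, ds$sigma_lab, curve, window = window)
  raw <- rowSums(dens)
  vals <- if (smoothing > 1) moving_average(raw, smoothing) else raw
  structure(list(calbp = attr(dens, "calbp"), values = vals,
                 n_dates = nrow(ds), smoothing = smoothing,
                 window = sort(as.numeric(window)),
                 label = if (is.null(label)) "spd" else label),
            class = "spd_series")
}

# Internal: SPD directly from numeric age/error vectors (simulation path).
spd_from_vectors <- function(c14_age, sigma_lab, curve, window, smoothing) {
  dens <- calibrate_matrix(c14_age, sigma_lab, curve, window = window)
  raw <- rowSums(dens)
  vals <- if (smoothing > 1) moving_average(raw, smoothing) else raw
  list(calbp = attr(dens, "calbp"), values = vals)
}

#' Slice an SPD to a calendar sub-window
#'
#' @param spd An `spd_series`.
#' @param interval Cal BP interval (either order); years outside the grid
#'   are dropped, an empty overlap is an error.
#' @return The sliced `spd_series` (orientation and metadata preserved).
#' @export
window_series <- function(spd, interval) {
  stopifnot(inherits(spd, "spd_series"))
  interval <- sort(as.numeric(interval))
  sel <- spd$calbp >= interval[1] & spd$calbp <= interval[2]
  if (!any(sel))
    stop("interval [", interval[1], ", ", interval[2],
         "] does not overlap the SPD grid", call. = FALSE)
  structure(list(calbp = spd$calbp[sel], values = spd$values[sel],
                 n_dates = spd$n_dates, smoothing = spd$smoothing,
                 window = interval, label = spd$label),
            class = "spd_series")
}

#' Write an SPD as a two-column CSV (cal BP, value)
#' @param spd An `spd_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spd_csv <- function(spd, path) {
  stopifnot(inherits(spd, "spd_series"))
  utils::write.csv(data.frame(calbp = spd$calbp, value = spd$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an SPD from a two-column CSV written by [write_spd_csv()]
#' @param path CSV with columns `calbp`, `value`.
#' @param label Series label.
#' @return An `spd_series` (with unknown `n_dates`/`smoothing` set to NA).
#' @export
read_spd_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("calbp", "value") %in% names(df)))
    stop("SPD CSV needs columns calbp and value", call. = FALSE)
  ord <- order(df$calbp, decreasing = TRUE)
  structure(list(calbp = df$calbp[ord], values = df$value[ord],
                 n_dates = NA_integer_, smoothing = NA_real_,
                 window = range(df$calbp), label = label),
            class = "spd_series")
}

#' @export
print.spd_series <- function(x, ...) {
  cat("SPD:", x$label, "\n  grid:", max(x$calbp), "-", min(x$calbp),
      "cal BP (annual, oldest first)\n  dates:", x$n_dates,
      " smoothing:", x$smoothing, "yr\n  total mass:",
      format(sum(x$values), digits = 6), "\n")
  invisible(x)
}

#' @export
as.data.frame.spd_series <- function(x, ...) {
  data.frame(calbp = x$calbp, value = x$values)
}
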