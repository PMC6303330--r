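#' Construct a calibration curve from knots
#'
#' A calibration curve maps calendar years (cal BP, before 1950; larger is
#' older) to expected radiocarbon ages with a 1-sigma curve error. The knots
#' are resampled by linear interpolation onto an annual calendar grid, the
#' resolution shared by every downstream series in the package.
#'
#' @param calbp Integer-valued calendar years BP of the knots.
#' @param c14 Radiocarbon ages (14C yr BP) at the knots.
#' @param error 1-sigma curve errors (14C yr) at the knots; all positive.
#' @param cal_range Length-2 numeric, the calendar interval (either order)
#'   to cover with the annual grid. The knots must span it.
#' @param name Text label for the curve.
#' @return An object of class `cal_curve`: a list with `knots` (data frame,
#'   oldest first), `grid` (annual data frame with columns `calbp`, `mu`,
#'   `sigma`, oldest first), `cal_range` and `name`.
#' @examples
#' cc <- cal_curve(c(20000, 15000, 10000), c(17000, 13000, 9000),
#'                 c(40, 30, 20), cal_range = c(10000, 20000))
#' cal_curve_lookup(cc, 12500)
#' @export
cal_curve <- function(calbp, c14, error, cal_range = c(9500, 20500),
                      name = "curve") {
  if (length(calbp) < 2L)
    stop("calibration curve needs at least two knots", call. = FALSE)
  if (length(c14) != length(calbp) || length(error) != length(calbp))
    stop("calbp, c14 and error must have equal length", call. = FALSE)
  d <- diff(calbp)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("knot cal BP values must be strictly monotonic", call. = FALSE)
  if (any(!is.finite(error)) || any(error <= 0))
    stop("curve errors must be positive", call. = FALSE)
  cal_range <- sort(as.numeric(cal_range))
  ord <- order(calbp, decreasing = TRUE)   # store oldest -> youngest
  knots <- data.frame(calbp = calbp[ord], c14 = c14[ord], error = error[ord])
  if (min(knots$calbp) > cal_range[1] || max(knots$calbp) < cal_range[2])
    stop("knots do not span the requested cal range [", cal_range[1], ", ",
         cal_range[2], "]", call. = FALSE)
  grid_years <- seq(cal_range[2], cal_range[1], by = -1)
  asc <- knots[order(knots$calbp), ]
  mu <- stats::approx(asc$calbp, asc$c14, xout = grid_years)$y
  sg <- stats::approx(asc$calbp, asc$error, xout = grid_years)$y
  structure(list(knots = knots,
                 grid = data.frame(calbp = grid_years, mu = mu, sigma = sg),
                 cal_range = cal_range, name = name),
            class = "cal_curve")
}

#' Read an IntCal-style ".14c" calibration curve file
#'
#' The format is plain text: comment lines starting with `#`, then rows of
#' comma- or whitespace-separated columns CAL BP, 14C age, error. Additional
#' columns are ignored.
#'
#' @param path Path to the curve file.
#' @param cal_range Calendar interval the annual grid must cover.
#' @param name Label; defaults to the file name.
#' @return A [cal_curve] object.
#' @export
read_cal_curve <- function(path, cal_range = c(9500, 20500),
                           name = basename(path)) {
  if (!file.exists(path)) stop("no such curve file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (length(keep) == 0L)
    stop("curve file contains no data rows: ", path, call. = FALSE)
  fields <- strsplit(trimws(gsub(",", " ", keep)), "\\s+")
  if (any(vapply(fields, length, 1L) < 3L))
    stop("curve rows must have at least 3 columns (cal BP, 14C age, error)",
         call. = FALSE)
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  calbp <- num(1); c14 <- num(2); err <- num(3)
  if (anyNA(calbp) || anyNA(c14) || anyNA(err))
    stop("non-numeric values in curve file: ", path, call. = FALSE)
  cal_curve(calbp, c14, err, cal_range = cal_range, name = name)
}

#' Write a calibration curve's knots to a ".14c" file
#'
#' Values are written with full precision so that reading the file back
#' reproduces the knots exactly.
#'
#' @param curve A [cal_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cal_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  k <- curve$knots
  lines <- c(paste0("# ", curve$name),
             "# CAL BP, 14C age, Error",
             sprintf("%.17g,%.17g,%.17g", k$calbp, k$c14, k$error))
  writeLines(lines, path)
  invisible(path)
}

#' Look up curve mean and error at arbitrary calendar years
#'
#' Linear interpolation of both the 14C mean and the 1-sigma error between
#' knots; exact at knot positions.
#'
#' @param curve A [cal_curve].
#' @param calbp Calendar years BP (may be non-integer, must lie within the
#'   knot span).
#' @return Data frame with columns `calbp`, `mu`, `sigma`.
#' @export
cal_curve_lookup <- function(curve, calbp) {
  stopifnot(inherits(curve, "cal_curve"))
  asc <- curve$knots[order(curve$knots$calbp), ]
  if (any(calbp < min(asc$calbp)) || any(calbp > max(asc$calbp)))
    stop("lookup outside the curve's knot span", call. = FALSE)
  data.frame(calbp = calbp,
             mu = stats::approx(asc$calbp, asc$c14, xout = calbp)$y,
             sigma = stats::approx(asc$calbp, asc$error, xout = calbp)$y)
}

# Annual grid of a curve, optionally restricted to a sub-window (cal BP).
curve_grid <- function(curve, window = NULL) {
  g <- curve$grid
  if (is.null(window)) return(g)
  window <- sort(as.numeric(window))
  sel <- g$calbp >= window[1] & g$calbp <= window[2]
  if (!any(sel))
    stop("window [", window[1], ", ", window[2],
         "] does not overlap the curve grid", call. = FALSE)
  if (window[1] < min(g$calbp) || window[2] > max(g$calbp))
    stop("window extends beyond the curve grid", call. = FALSE)
  g[sel, , drop = FALSE]
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve:", x$name, "\n")
  cat("  knots:", nrow(x$knots), " spanning",
      max(x$knots$calbp), "-", min(x$knots$calbp), "cal BP\n")
  cat("  annual grid:", x$cal_range[2], "-", x$cal_range[1],
      "cal BP (oldest first)\n")
  invisible(x)
}
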