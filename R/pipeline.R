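# Pipeline orchestration: a validated run configuration and a single entry
# point chaining dates -> vetting -> SPD -> breakpoint -> null model ->
# Monte-Carlo test, with JSON/CSV export. The command-line wrapper at
# inst/cli/c14pop.R is a thin shell over these functions.

#' Build and validate a pipeline run configuration
#'
#' Defaults reproduce the standard analysis settings: SPDs built on a
#' 20.0--10.0 ka annual grid with 200-year smoothing, deviations flagged
#' over 15.0--10.0 ka, correlations over 15.0--11.7 ka, 500 simulations at
#' alpha = 0.05, and an exponential null.
#'
#' @param curve_path Path to a ".14c" calibration-curve file.
#' @param dates_path Path to a radiocarbon date CSV.
#' @param region Optional region filter (see [filter_region()]).
#' @param grid_window,reporting_window,correlation_window Cal BP intervals;
#'   the latter two must nest inside the grid window.
#' @param smoothing Moving-average width in years.
#' @param nsim,alpha Monte-Carlo settings (`nsim >= 2`).
#' @param null_kind `"exponential"` or `"logistic"`.
#' @param taphonomy `NULL`, or a list `a, b, c` to correct the SPD before
#'   testing (see [taphonomic_correct()]).
#' @param vet Named list of arguments for [vet_dates()].
#' @param seed Master integer seed; all per-simulation seeds derive from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(curve_path = NULL, dates_path = NULL, region = NULL,
                       grid_window = c(10000, 20000),
                       reporting_window = c(10000, 15000),
                       correlation_window = c(11700, 15000),
                       smoothing = 200, nsim = 500, alpha = 0.05,
                       null_kind = c("exponential", "logistic"),
                       taphonomy = NULL, vet = list(), seed = 1) {
  null_kind <- match.arg(null_kind)
  grid_window <- sort(as.numeric(grid_window))
  reporting_window <- sort(as.numeric(reporting_window))
  correlation_window <- sort(as.numeric(correlation_window))
  nest <- function(w) w[1] >= grid_window[1] && w[2] <= grid_window[2]
  if (!nest(reporting_window) || !nest(correlation_window))
    stop("reporting and correlation windows must nest inside the grid window",
         call. = FALSE)
  if (nsim < 2) stop("nsim must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(curve_path = curve_path, dates_path = dates_path,
                 region = region, grid_window = grid_window,
                 reporting_window = reporting_window,
                 correlation_window = correlation_window,
                 smoothing = smoothing, nsim = nsim, alpha = alpha,
                 null_kind = null_kind, taphonomy = taphonomy, vet = vet,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tf))
}

#' Run the full demographic null-model pipeline
#'
#' Reads (or accepts) a curve and date table, vets the dates, builds the
#' SPD, locates the breakpoint (falling back to a full-window exponential
#' fit when the deviance profile has no interior optimum), fits the chosen
#' null, optionally applies taphonomic correction to observed and null
#' series alike, and runs the Monte-Carlo test. Every stage failure is
#' reported with the stage name.
#'
#' @param config A [run_config].
#' @param curve,dates Optional in-memory [cal_curve]/[date_set] overriding
#'   the configured paths.
#' @return List of class `pipeline_result` with the vetted dates and audit,
#'   the SPD, the breakpoint fit, the null model, the `mc_test_result`,
#'   the terminal bust onset, the config and its md5 hash.
#' @export
run_model_pipeline <- function(config, curve = NULL, dates = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(curve))
    curve <- stage("curve", read_cal_curve(config$curve_path,
      cal_range = config$grid_window + c(-500, 500)))
  if (is.null(dates))
    dates <- stage("dates", read_dates_csv(config$dates_path))
  vetted <- stage("vetting", do.call(vet_dates, c(list(dates), config$vet)))
  if (!is.null(config$region))
    vetted <- stage("region", filter_region(vetted, config$region))
  if (nrow(vetted) == 0L)
    stop("stage [vetting]: no dates remain after vetting", call. = FALSE)
  spd <- stage("spd", build_spd(vetted, curve, window = config$grid_window,
                                smoothing = config$smoothing))
  if (!is.null(config$taphonomy))
    spd <- stage("taphonomy", do.call(taphonomic_correct,
                                      c(list(spd), config$taphonomy)))
  bp <- stage("breakpoint", fit_breakpoint(spd,
    search = c(config$grid_window[1] + 500, config$grid_window[2] - 500)))
  bp_year <- if (bp$interior_optimum) bp$breakpoint_year
             else min(spd$calbp) + 10   # no decline: fit ~ full window
  null <- stage("null", switch(config$null_kind,
    exponential = fit_exponential_null(spd, breakpoint = bp_year),
    logistic = fit_logistic_null(spd, breakpoint = bp_year,
                                 seed = config$seed)))
  mc <- stage("mctest", run_model_test(spd, null, curve,
    sigma_pool = vetted$sigma_lab, nsim = config$nsim,
    alpha = config$alpha, reporting_window = config$reporting_window,
    seed = config$seed))
  structure(list(dates = vetted, audit = vet_audit(vetted), spd = spd,
                 breakpoint = bp, null = null, mc = mc,
                 terminal_bust_onset = terminal_bust_onset(mc),
                 config = config, config_hash = config_hash(config)),
            class = "pipeline_result")
}

#' Write the artifacts of a pipeline run
#'
#' Emits `result.json` (test summary, audit, seed, config hash),
#' `spd.csv`, `null.csv` and `peryear.csv` under `dir`.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = unclass(result$config), config_hash = result$config_hash,
         audit = as.list(result$audit),
         breakpoint = unclass(result$breakpoint),
         global_p = result$mc$global_p,
         boom_intervals = result$mc$boom_intervals,
         bust_intervals = result$mc$bust_intervals,
         terminal_bust_onset = result$terminal_bust_onset,
         seed = result$config$seed),
    file.path(dir, "result.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write_spd_csv(result$spd, file.path(dir, "spd.csv"))
  write_null_csv(result$null, file.path(dir, "null.csv"))
  utils::write.csv(mc_result_table(result$mc),
                   file.path(dir, "peryear.csv"), row.names = FALSE)
  invisible(dir)
}

#' Batch-calibrate a date table to per-year densities
#'
#' @param dates_path CSV of dates.
#' @param curve_path ".14c" curve file.
#' @param out_dir Output directory: one `<lab_id>.csv` density per date
#'   plus an `index.csv`.
#' @param window Optional cal BP window.
#' @return Data frame index (lab_id, file, modal year), invisibly.
#' @export
batch_calibrate <- function(dates_path, curve_path, out_dir,
                            window = NULL) {
  ds <- read_dates_csv(dates_path)
  curve <- read_cal_curve(curve_path,
                          cal_range = if (is.null(window)) c(9500, 20500)
                                      else sort(window) + c(-500, 500))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- lapply(seq_len(nrow(ds)), function(i) {
    d <- calibrate_date(ds$c14_age[i], ds$sigma_lab[i], curve,
                        window = window, date_ref = ds$lab_id[i])
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                        ds$lab_id[i]), ".csv"))
    write_cal_density(d, f)
    data.frame(lab_id = ds$lab_id[i], file = basename(f),
               modal_calbp = d$calbp[which.max(d$prob)])
  })
  idx <- do.call(rbind, idx)
  utils::write.csv(idx, file.path(out_dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Correlate two SPD CSV files
#'
#' @param spd_a_path,spd_b_path Two-column SPD CSVs on the same annual grid.
#' @param window Cal BP correlation window.
#' @return A `correlation_result`.
#' @export
correlate_spd_files <- function(spd_a_path, spd_b_path,
                                window = c(11700, 15000)) {
  a <- read_spd_csv(spd_a_path)
  b <- read_spd_csv(spd_b_path)
  spearman_spd(a, b, window = window)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (config", substr(x$config_hash, 1, 8), ")\n")
  print(x$breakpoint)
  print(x$mc)
  invisible(x)
}
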