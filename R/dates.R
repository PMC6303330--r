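#' Construct a set of radiocarbon dates
#'
#' A `date_set` is a data frame of laboratory measurements with metadata
#' used for vetting and regional/taxon filtering. Mandatory columns are
#' `lab_id`, `c14_age` and `sigma_lab`; the optional columns `material`,
#' `taxon`, `context` (one of archaeological/paleontological/geological),
#' `state_province`, `latitude`, `anomalous`, `kill_site` and
#' `individual_id` default to missing/unset.
#'
#' @param df Data frame with at least `lab_id`, `c14_age`, `sigma_lab`.
#' @param label Text label for the set.
#' @param provenance Free-text provenance note.
#' @return A data frame of class `date_set`.
#' @export
date_set <- function(df, label = "dates", provenance = NA_character_) {
  need <- c("lab_id", "c14_age", "sigma_lab")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  defaults <- list(material = NA_character_, taxon = NA_character_,
                   context = NA_character_, state_province = NA_character_,
                   latitude = NA_real_, anomalous = FALSE, kill_site = FALSE,
                   individual_id = NA_character_)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  df$c14_age <- as.numeric(df$c14_age)
  df$sigma_lab <- as.numeric(df$sigma_lab)
  df$anomalous <- as_flag(df$anomalous)
  df$kill_site <- as_flag(df$kill_site)
  bad <- which(!is.finite(df$c14_age) | df$c14_age <= 0)
  if (length(bad))
    stop("non-positive or missing c14_age in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$sigma_lab) | df$sigma_lab <= 0)
  if (length(bad))
    stop("non-positive or missing sigma_lab in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  ds <- df[, c(need, names(defaults))]
  rownames(ds) <- NULL
  structure(ds, label = label, provenance = provenance,
            class = c("date_set", "data.frame"))
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  u <- toupper(trimws(as.character(x)))
  u %in% c("TRUE", "T", "1", "YES", "Y")
}

#' Read a radiocarbon date table from CSV
#'
#' @param path CSV file with a header naming at least `lab_id`, `c14_age`
#'   and `sigma_lab`; unknown columns are ignored, optional columns get
#'   defaults.
#' @param label,provenance Passed to [date_set()]; provenance defaults to
#'   the file path.
#' @return A [date_set].
#' @export
read_dates_csv <- function(path, label = basename(path), provenance = path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_id", "c14_age", "sigma_lab")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("c14_age", "sigma_lab")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("unparseable ", col, " in row(s) ", paste(bad, collapse = ", "),
           " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  date_set(df, label = label, provenance = provenance)
}

#' Write a date set to CSV
#' @param ds A [date_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dates_csv <- function(ds, path) {
  stopifnot(inherits(ds, "date_set"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Vet a date table
#'
#' Applies the standard inclusion rules in a fixed order so that audit
#' counts are deterministic: (1) duplicate `lab_id` rows dropped (first
#' kept); (2) rows flagged anomalous dropped; (3) rows whose `context` is
#' in `drop_contexts` dropped; (4) kill/scavenging-site rows dropped when
#' `drop_kill_sites`; (5) collapsed to one date per `individual_id` (first
#' kept). Each removal is attributed to the first matching rule. The audit
#' is attached as attribute `"audit"` (named integer vector, one entry per
#' rule plus `retained`).
#'
#' @param ds A [date_set].
#' @param drop_anomalous Drop rows flagged anomalous (default TRUE).
#' @param drop_contexts Character vector of contexts to exclude, e.g.
#'   `c("paleontological", "geological")` when vetting an anthropogenic set.
#' @param drop_kill_sites Drop kill/scavenging-associated rows (used for
#'   paleontological megafauna sets so human-associated specimens do not
#'   inflate the record).
#' @param dedup_individuals Keep a single date per `individual_id`.
#' @return The vetted [date_set] with an `"audit"` attribute. May be empty;
#'   the audit records it.
#' @seealso [vet_audit()]
#' @export
vet_dates <- function(ds, drop_anomalous = TRUE, drop_contexts = character(),
                      drop_kill_sites = FALSE, dedup_individuals = TRUE) {
  stopifnot(inherits(ds, "date_set"))
  n0 <- nrow(ds)
  removed <- c(duplicate_lab_id = 0L, anomalous = 0L, context = 0L,
               kill_site = 0L, individual_dedup = 0L)
  keep <- rep(TRUE, n0)

  hit <- keep & duplicated(ds$lab_id)
  removed["duplicate_lab_id"] <- sum(hit); keep[hit] <- FALSE

  if (drop_anomalous) {
    hit <- keep & ds$anomalous
    removed["anomalous"] <- sum(hit); keep[hit] <- FALSE
  }
  if (length(drop_contexts)) {
    hit <- keep & !is.na(ds$context) & ds$context %in% drop_contexts
    removed["context"] <- sum(hit); keep[hit] <- FALSE
  }
  if (drop_kill_sites) {
    hit <- keep & ds$kill_site
    removed["kill_site"] <- sum(hit); keep[hit] <- FALSE
  }
  if (dedup_individuals) {
    id <- ds$individual_id
    surv <- which(keep & !is.na(id))
    hit_idx <- surv[duplicated(id[surv])]
    removed["individual_dedup"] <- length(hit_idx); keep[hit_idx] <- FALSE
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- date_set(as.data.frame(out), label = attr(ds, "label"),
                  provenance = attr(ds, "provenance"))
  attr(out, "audit") <- c(input = n0, removed, retained = sum(keep))
  out
}

#' Retrieve the audit of a vetted date set
#' @param ds A [date_set] returned by [vet_dates()].
#' @return Named integer vector of per-rule removal counts.
#' @export
vet_audit <- function(ds) attr(ds, "audit")

# state/province normalisation ------------------------------------------------

.province_abb <- c(ALBERTA = "AB", `BRITISH COLUMBIA` = "BC", MANITOBA = "MB",
  `NEW BRUNSWICK` = "NB", `NEWFOUNDLAND AND LABRADOR` = "NL",
  `NOVA SCOTIA` = "NS", ONTARIO = "ON", `PRINCE EDWARD ISLAND` = "PE",
  QUEBEC = "QC", SASKATCHEWAN = "SK", YUKON = "YT",
  `NORTHWEST TERRITORIES` = "NT", NUNAVUT = "NU")

normalize_state <- function(x) {
  u <- toupper(trimws(as.character(x)))
  abb <- c(stats::setNames(datasets::state.abb, toupper(datasets::state.name)),
           .province_abb)
  known <- u %in% c(datasets::state.abb, .province_abb)
  out <- ifelse(known, u, unname(abb[u]))
  out
}

.regions <- list(
  southwest = c("CA", "NV", "UT", "AZ", "NM"),
  great_lakes = c("ON", "NY", "PA", "OH", "MI", "IN", "IL", "WI", "MN"))

#' Filter a date set to a named study region
#'
#' `"southwest"` keeps California, Nevada, Utah, Arizona and New Mexico;
#' `"great_lakes"` keeps the states and provinces bordering any Great Lake
#' (Ontario, New York, Pennsylvania, Ohio, Michigan, Indiana, Illinois,
#' Wisconsin, Minnesota); `"contiguous_us"` keeps rows with latitude south
#' of 52 degrees N. State/province names or postal abbreviations are both
#' accepted.
#'
#' @param ds A [date_set].
#' @param region One of `"southwest"`, `"great_lakes"`, `"contiguous_us"`.
#' @return The filtered [date_set].
#' @export
filter_region <- function(ds,
                          region = c("southwest", "great_lakes",
                                     "contiguous_us")) {
  stopifnot(inherits(ds, "date_set"))
  region <- match.arg(region)
  keep <- if (region == "contiguous_us") {
    !is.na(ds$latitude) & ds$latitude < 52
  } else {
    st <- normalize_state(ds$state_province)
    !is.na(st) & st %in% .regions[[region]]
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  date_set(as.data.frame(out),
           label = paste0(attr(ds, "label"), " [", region, "]"),
           provenance = attr(ds, "provenance"))
}

#' Split a date set by taxon, keeping well-represented taxa
#'
#' A date belongs to the compilation window when its modal calibrated year
#' falls inside it; a taxon is kept when it has strictly more than
#' `min_dates` member dates. The default threshold of 20 reproduces the
#' "more than 20 dates" compilation rule used for late-Pleistocene SPDs.
#'
#' @param ds A vetted [date_set] with `taxon` populated.
#' @param curve A [cal_curve] used to locate each date's modal year.
#' @param window Cal BP interval of the compilation window.
#' @param min_dates Strict lower bound on per-taxon date counts.
#' @return Named list mapping taxon to its [date_set] of in-window dates.
#' @export
select_taxa <- function(ds, curve, window = c(10000, 20000), min_dates = 20) {
  stopifnot(inherits(ds, "date_set"), min_dates >= 1)
  if (nrow(ds) == 0L) return(stats::setNames(list(), character(0)))
  window <- sort(as.numeric(window))
  modal <- vapply(seq_len(nrow(ds)), function(i) {
    tryCatch({
      d <- calibrate_date(ds$c14_age[i], ds$sigma_lab[i], curve)
      d$calbp[which.max(d$prob)]
    }, error = function(e) NA_real_)   # outside curve support: not in window
  }, numeric(1))
  inw <- !is.na(modal) & modal >= window[1] & modal <= window[2] &
    !is.na(ds$taxon)
  tab <- table(ds$taxon[inw])
  taxa <- names(tab)[tab > min_dates]
  out <- lapply(taxa, function(tx) {
    sub <- ds[inw & ds$taxon == tx, , drop = FALSE]
    rownames(sub) <- NULL
    date_set(as.data.frame(sub), label = tx, provenance = attr(ds, "provenance"))
  })
  stats::setNames(out, taxa)
}

#' @export
print.date_set <- function(x, ...) {
  cat("Date set:", attr(x, "label"), "(", nrow(x), "dates )\n")
  if (!is.null(attr(x, "audit"))) {
    a <- attr(x, "audit")
    cat("  vetted:", paste(names(a), a, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}
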