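test_that("date CSVs read with defaults and fail loudly on bad input", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(lab_id = c("A", "B", "C"),
                       c14_age = c(12000, 12500, 13000),
                       sigma_lab = c(40, 50, 60)), tf, row.names = FALSE)
  ds <- read_dates_csv(tf)
  expect_s3_class(ds, "date_set")
  expect_equal(nrow(ds), 3)
  expect_false(any(ds$anomalous))
  expect_true(all(is.na(ds$taxon)))

  write.csv(data.frame(lab_id = "A", c14_age = 12000), tf, row.names = FALSE)
  expect_error(read_dates_csv(tf), "sigma_lab")

  write.csv(data.frame(lab_id = c("A", "B"), c14_age = c("12000", "abc"),
                       sigma_lab = c(40, 50)), tf, row.names = FALSE)
  expect_error(read_dates_csv(tf), "row\\(s\\) 2")
})

test_that("vetting removes rows in a fixed order with a summing audit", {
  ds <- vetting_fixture()   # 10 rows: 2 lab-id dups, 1 anomalous, 1 geological
  v <- vet_dates(ds, drop_contexts = c("paleontological", "geological"))
  expect_equal(nrow(v), 6)
  a <- vet_audit(v)
  expect_equal(unname(a["duplicate_lab_id"]), 2L)
  expect_equal(unname(a["anomalous"]), 1L)
  expect_equal(unname(a["context"]), 1L)
  # audit sums: removals account exactly for the row difference
  expect_equal(unname(a["input"] - a["retained"]),
               sum(a[c("duplicate_lab_id", "anomalous", "context",
                       "kill_site", "individual_dedup")]))
})

test_that("vetting is idempotent and clean tables pass through", {
  ds <- vetting_fixture()
  v1 <- vet_dates(ds, drop_contexts = "geological")
  v2 <- vet_dates(v1, drop_contexts = "geological")
  expect_equal(unname(vet_audit(v2)["retained"]),
               unname(vet_audit(v1)["retained"]))
  # idempotent on the rows (audits differ: the second pass removes nothing)
  strip <- function(x) { attr(x, "audit") <- NULL; as.data.frame(x) }
  expect_equal(strip(v2), strip(v1))

  clean <- one_date(12000, 50)
  vclean <- vet_dates(clean)
  attr(vclean, "audit") <- NULL
  expect_equal(as.data.frame(vclean), as.data.frame(clean))
})

test_that("one date per individual is kept; kill sites drop on request", {
  ds <- date_set(data.frame(
    lab_id = c("L1", "L2", "L3", "L4"),
    c14_age = c(12000, 12100, 12200, 12300),
    sigma_lab = rep(40, 4),
    kill_site = c(FALSE, TRUE, FALSE, FALSE),
    individual_id = c("ind1", NA, "ind1", "ind2")))
  v <- vet_dates(ds, drop_kill_sites = TRUE)
  expect_equal(v$lab_id, c("L1", "L4"))
  expect_equal(unname(vet_audit(v)["kill_site"]), 1L)
  expect_equal(unname(vet_audit(v)["individual_dedup"]), 1L)
})

test_that("regional filters follow the state/province definitions", {
  ds <- date_set(data.frame(
    lab_id = paste0("L", 1:6),
    c14_age = rep(12000, 6),
    sigma_lab = rep(40, 6),
    state_province = c("AZ", "Ontario", "TX", "new york", "NV", "Alberta"),
    latitude = c(34, 44, 31, 43, 39, 53)))
  sw <- filter_region(ds, "southwest")
  expect_setequal(sw$lab_id, c("L1", "L5"))      # AZ, NV
  gl <- filter_region(ds, "great_lakes")
  expect_setequal(gl$lab_id, c("L2", "L4"))      # Ontario, New York
  us <- filter_region(ds, "contiguous_us")
  expect_false("L6" %in% us$lab_id)              # 53 N excluded
  expect_equal(nrow(us), 5)
  expect_error(filter_region(ds, "atlantis"))
})

test_that("taxa are selected by a strict per-window date-count threshold", {
  cc <- exact_curve()
  mk <- function(taxon, n, age0) data.frame(
    lab_id = paste0(taxon, seq_len(n)), c14_age = age0 + seq_len(n),
    sigma_lab = 50, taxon = taxon)
  ds <- date_set(rbind(mk("mammoth", 21, 12000),   # 21 dates -> included
                       mk("mastodon", 20, 12500),  # 20 dates -> excluded
                       mk("sloth", 25, 30000)))    # outside window
  sel <- select_taxa(ds, cc, window = c(10000, 20000), min_dates = 20)
  expect_equal(names(sel), "mammoth")
  expect_equal(nrow(sel$mammoth), 21)

  empty <- date_set(data.frame(lab_id = character(0),
                               c14_age = numeric(0),
                               sigma_lab = numeric(0)))
  expect_equal(length(select_taxa(empty, cc)), 0)
})
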