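test_that("thermal ranges validate and measure correctly", {
  tr <- thermal_range(18, 25)
  expect_equal(tolerance_width(tr), 7)
  expect_equal(midpoint(tr), 21.5)
  expect_equal(tolerance_width(20, 20), 0)
  expect_equal(tolerance_width(17.5, 22.0), 4.5)
  expect_equal(midpoint(20, 20), 20)
  expect_equal(midpoint(0, 4), 2)
  expect_error(thermal_range(22, 18), "t_min > t_max")
  expect_warning(thermal_range(-10, 3), "envelope")
})

test_that("the stage chart has 29 well-ordered Devonian-Triassic slices", {
  st <- stage_table()
  expect_equal(nrow(st), 29)
  expect_true(all(st$age_min_ma < st$age_max_ma))
  # ordered oldest first, adjacent stages non-overlapping (shared boundaries)
  expect_true(all(diff(st$age_max_ma) < 0))
  expect_true(all(st$age_max_ma[-1] <= st$age_min_ma[-nrow(st)]))
  expect_equal(normalize_stage(c(" pragian ", "Changxingian", "no-such")),
               c("Pragian", "Changhsingian", NA))
})

test_that("read_occurrences round-trips valid rows and logs bad ones", {
  rec <- make_records()
  f <- tempfile(fileext = ".csv")
  write_occurrences(rec, f)
  got <- read_occurrences(f)
  expect_equal(got$n_skipped, 0)
  expect_equal(got$records, rec)

  # inverted range and unparseable temperature are skipped with reasons
  bad <- rec
  bad$t_min_c[2] <- 22; bad$t_max_c[2] <- 18
  bad$t_min_c[4] <- NA
  write_occurrences(bad, f)
  got <- read_occurrences(f)
  expect_equal(got$n_skipped, 2)
  expect_equal(nrow(got$records), 3)
  expect_setequal(got$skipped$reason,
                  c("inverted_thermal_range", "unparseable_temperature"))
  expect_equal(got$skipped$row, c(2, 4))
})

test_that("column mapping renames source columns and flags missing ones", {
  rec <- make_records()
  names(rec)[names(rec) == "paleolat"] <- "plat"
  f <- tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE)
  got <- read_occurrences(f, column_map = c(paleolat = "plat"))
  expect_equal(got$records$paleolat[1], 12)
  expect_error(read_occurrences(f, column_map = c(paleolat = "nope")),
               "nope")
})

test_that("free-text bathymetry falls back to keywords, else unknown", {
  rec <- make_records(depth = c("shallow", "upper bathyal", "reef flat",
                                "deep basinal", "no idea"))
  f <- tempfile(fileext = ".csv")
  write_occurrences(rec, f)
  got <- read_occurrences(f)
  expect_equal(got$records$depth_class,
               c("shallow", "deep", "shallow", "deep", "unknown"))
})

test_that("relational deposit loader joins, counts and skips dangling keys", {
  d <- make_mini_deposit()
  got <- load_paleosib_deposit(d)
  expect_equal(got$totals$n_records, 4)
  expect_equal(got$totals$n_collections, 2)
  expect_equal(got$totals$n_taxa, 3)
  expect_equal(got$n_dangling, 0)
  expect_equal(sort(unique(got$records$taxon_name)),
               c("Cyrtospirifer", "Favosites", "Spirifer"))

  d2 <- make_mini_deposit(drop_collection = TRUE)
  got2 <- load_paleosib_deposit(d2)
  expect_equal(got2$totals$n_records, 2)
  expect_equal(got2$n_dangling, 2)
})

test_that("deposit loading is permutation-invariant and rejects duplicate ids", {
  d <- make_mini_deposit()
  occ <- read.csv(file.path(d, "occurrences.csv"))
  write.csv(occ[rev(seq_len(nrow(occ))), ], file.path(d, "occurrences.csv"),
            row.names = FALSE)
  got <- load_paleosib_deposit(d)
  expect_equal(got$totals, list(n_records = 4, n_collections = 2, n_taxa = 3))

  occ$record_id[2] <- occ$record_id[1]
  write.csv(occ, file.path(d, "occurrences.csv"), row.names = FALSE)
  expect_error(load_paleosib_deposit(d), "duplicate")
})

test_that("bin estimates round-trip through the delimited writer", {
  set.seed(7)
  lat <- runif(40, 5, 45)
  tmin <- round(runif(40, 12, 20), 1)
  rec <- make_records(paleolat = lat, t_min = tmin, t_max = tmin + 3)
  fit <- paleotherm(rec)
  f <- tempfile(fileext = ".csv")
  write_bin_estimates(fit$estimates, f)
  lines <- readLines(f)
  expect_equal(lines[1], "Stage,Paleolatitude,n,n_int,HLM,Q1,Q3,IQR")
  expect_equal(length(lines), nrow(fit$estimates) + 1)
  back <- read_bin_estimates(f)
  expect_equal(back$hlm, round(fit$estimates$hlm, 3))
  expect_equal(back$q1, round(fit$estimates$q1, 3))
  # write/read/write is bit-stable at the 3-decimal precision
  f2 <- tempfile(fileext = ".csv")
  write_bin_estimates(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_bin_estimates(fit$estimates[0, ], f), "no estimates")
})
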