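test_that("tolerance classes split at inclusive cutoffs", {
  cfg <- screening_config()
  expect_equal(classify_tolerance(2.5, cfg), "narrow")
  expect_equal(classify_tolerance(4.0, cfg), "moderate")
  expect_equal(classify_tolerance(6.0, cfg), "excluded")
  # boundary semantics: exactly 3 is narrow, exactly 5 is moderate
  expect_equal(classify_tolerance(c(3, 5), cfg), c("narrow", "moderate"))
})

test_that("admissibility filter removes wide and deep records with a full tally", {
  rec <- make_records(
    paleolat = c(12, 13, 14, 15, 16),
    t_min = c(20, 20, 20, 20, 20),
    t_max = c(22, 26, 23, 24, 23),       # record 2 has width 6
    depth = c("shallow", "shallow", "deep", "shallow", "shallow")
  )
  got <- filter_admissible(rec, screening_config())
  expect_equal(nrow(got$records), 3)
  expect_equal(got$report$n_wide_excluded, 1)
  expect_equal(got$report$n_deepwater_excluded, 1)
  expect_equal(got$records$record_id, c("r001", "r004", "r005"))

  # all narrow and shallow: everything retained
  rec2 <- make_records()
  got2 <- filter_admissible(rec2, screening_config())
  expect_equal(got2$report$n_narrow, got2$report$n_input)
  expect_equal(nrow(got2$records), nrow(rec2))

  # empty input yields a zeroed report, not an error
  got3 <- filter_admissible(rec2[0, ], screening_config())
  expect_equal(got3$report$n_input, 0)
  expect_equal(nrow(got3$records), 0)
})

test_that("screening is idempotent and conserves counts (property)", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(1:60, 1)
    lat <- runif(n, 5, 45)
    tmin <- runif(n, 5, 25)
    w <- runif(n, 0, 8)
    rec <- make_records(paleolat = lat, t_min = tmin, t_max = tmin + w,
                        depth = sample(c("shallow", "deep"), n, replace = TRUE))
    got <- filter_admissible(rec, screening_config())
    r <- got$report
    expect_equal(r$n_input,
                 r$n_retained + r$n_wide_excluded + r$n_deepwater_excluded)
    expect_equal(r$n_after_tolerance, r$n_narrow + r$n_moderate)
    twice <- filter_admissible(got$records, screening_config())
    expect_equal(twice$records, got$records)
    expect_equal(twice$report$n_retained, r$n_retained)
  }
})

test_that("unknown depth class is retained with a warning", {
  rec <- make_records(depth = c("shallow", "unknown", "shallow", "shallow",
                                "unknown"))
  expect_warning(got <- filter_admissible(rec, screening_config()),
                 "unknown depth")
  expect_equal(nrow(got$records), 5)
})

test_that("grade classification follows the membership rule", {
  gs_mid <- grade_spec(red = c(18, 35), blue = c(0, 10), "midpoint")
  expect_equal(classify_grade(19, 23, gs_mid), "red")       # midpoint 21
  expect_equal(classify_grade(10, 12, gs_mid), "neither")   # midpoint 11
  gs_ov <- grade_spec(red = c(10, 35), blue = c(0, 10), "overlap")
  expect_equal(classify_grade(8, 12, gs_ov), "both")
  gs_gap <- grade_spec(red = c(12, 35), blue = c(0, 10), "midpoint")
  expect_equal(classify_grade(10, 12, gs_gap), "neither")   # midpoint 11
  gs_cont <- grade_spec(red = c(18, 35), blue = c(0, 20), "containment")
  expect_equal(classify_grade(18.5, 19.5, gs_cont), "both")
})

test_that("disjoint grades never classify 'both' under the midpoint rule", {
  set.seed(202)
  gs <- grade_spec(red = c(20, 35), blue = c(0, 15), "midpoint")
  tmin <- runif(500, -5, 40)
  g <- classify_grade(tmin, tmin + runif(500, 0, 5), gs)
  expect_false(any(g == "both"))
})

test_that("overlap exclusion removes exactly the planted overlappers", {
  set.seed(303)
  # 97 taxa safely inside one grade, 3 constructed to straddle both
  n <- 100
  gs <- grade_spec(red = c(20, 35), blue = c(0, 18), "overlap")
  tmin <- runif(n, 2, 12)                      # widths <= 5, inside blue
  tmax <- tmin + runif(n, 1, 5)
  tmin[1:3] <- c(17, 16.5, 17.5)               # straddle the 18-20 gap
  tmax[1:3] <- c(21, 20.5, 22.0)
  rec <- make_records(paleolat = runif(n, 5, 45), t_min = tmin, t_max = tmax,
                      taxon = sprintf("T%03d", 1:n))
  got <- exclude_overlapping(rec, gs, screening_config())
  expect_equal(sort(unique(got$excluded_taxa$taxon_name)),
               c("T001", "T002", "T003"))
  expect_equal(nrow(got$records), n - 3)
  # brute-force check: both-interval intersection agrees
  brute <- which(tmin <= 35 & tmax >= 20 & tmin <= 18 & tmax >= 0)
  expect_equal(sort(brute), 1:3)

  # disjoint ranges, all within one grade: a no-op
  got2 <- exclude_overlapping(rec[4:n, ], grade_spec(c(30, 40), c(0, 18),
                                                     "overlap"),
                              screening_config())
  expect_equal(nrow(got2$records), n - 3)
  expect_equal(nrow(got2$excluded_taxa), 0)

  # with exclude_overlap off the records pass through untouched
  off <- screening_config(exclude_overlap = FALSE)
  got3 <- exclude_overlapping(rec, gs, off)
  expect_equal(got3$records, rec)
})

test_that("screen_records folds overlap tallies into the report", {
  rec <- make_records(
    paleolat = c(12, 13, 22, 23, 31),
    t_min = c(20, 21, 17, 17, 15), t_max = c(23, 24, 21, 20, 18),
    taxon = c("A", "A", "B", "C", "D")
  )
  gs <- grade_spec(red = c(20, 35), blue = c(0, 21), "overlap")
  got <- screen_records(rec, screening_config(), gs)
  r <- got$report
  expect_equal(r$n_input,
               r$n_retained + r$n_wide_excluded + r$n_deepwater_excluded +
                 r$n_overlap_excluded)
})
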