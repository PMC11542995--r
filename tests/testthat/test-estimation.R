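test_that("bin assignment labels the nearest multiple, boundaries go up", {
  expect_equal(assign_bin(23.4), 20)
  expect_equal(assign_bin(25.0), 30)
  expect_equal(assign_bin(-12.0), -10)
  expect_equal(assign_bin(-25.0), -20)   # higher label on the boundary
  expect_equal(assign_bin(c(4.9, 15, 89)), c(0, 20, 90))
  cfg5 <- estimator_config(bin_width = 5)
  expect_equal(assign_bin(23.4, cfg5), 25)
})

test_that("identical intervals collapse with multiplicities summing to n", {
  rec <- make_records(paleolat = rep(12, 5),
                      t_min = c(10, 10, 12, 10, 12),
                      t_max = c(14, 14, 16, 14, 16))
  dd <- dedupe_intervals(rec)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$multiplicity, c(3, 2))
  expect_equal(sum(dd$multiplicity), 5)
  expect_equal(dd$midpoint, c(12, 14))   # sorted by midpoint
  # rounding to 0.01 C absorbs parsing noise
  rec2 <- make_records(paleolat = rep(12, 2),
                       t_min = c(10, 10.001), t_max = c(14, 14.004))
  expect_equal(nrow(dedupe_intervals(rec2)), 1)
  # all identical: one interval with full multiplicity
  rec3 <- make_records(paleolat = rep(12, 4), t_min = 10, t_max = 14)
  dd3 <- dedupe_intervals(rec3)
  expect_equal(nrow(dd3), 1)
  expect_equal(dd3$multiplicity, 4)
})

test_that("quartile conventions give the documented worked values", {
  cfg <- estimator_config()
  expect_equal(quartiles(1:5, cfg), c(q1 = 2, q3 = 4))
  expect_equal(quartiles(c(5, 5, 5), cfg), c(q1 = 5, q3 = 5))
  expect_equal(quartiles(c(1, 2, 3, 4, 100), cfg), c(q1 = 2, q3 = 4))
  expect_error(quartiles(numeric(0), cfg), "empty")
  # alternative conventions are selectable
  inc <- estimator_config(quartile_method = "inclusive")
  expect_equal(unname(quartiles(1:4, inc)), c(1.5, 3.5))
  exc <- estimator_config(quartile_method = "exclusive")
  expect_equal(unname(quartiles(1:5, exc)), c(1.5, 4.5))
})

test_that("Tukey fences remove the worked outliers and nothing else", {
  cfg <- estimator_config()
  tk <- tukey_filter(1:5, cfg)
  expect_equal(tk$retained, 1:5)
  expect_equal(length(tk$removed), 0)
  expect_equal(tk$fences, c(-1, 7))

  tk2 <- tukey_filter(c(1, 2, 3, 4, 100), cfg)
  expect_equal(tk2$retained, c(1, 2, 3, 4))
  expect_equal(tk2$removed, 100)
  expect_equal(tk2$fences, c(-1, 7))    # 4 + 1.5 * 2 = 7

  # degenerate: constant data, zero IQR, inclusive fences keep everything
  tk3 <- tukey_filter(c(5, 5, 5), cfg)
  expect_equal(tk3$retained, c(5, 5, 5))
  expect_equal(length(tk3$removed), 0)
})

test_that("Tukey filtering conserves the multiset and is idempotent inside fences", {
  set.seed(404)
  cfg <- estimator_config()
  for (rep in 1:50) {
    x <- rnorm(sample(3:40, 1), 15, sample(c(1, 5), 1))
    if (rep %% 3 == 0) x <- c(x, 100)
    tk <- tukey_filter(x, cfg)
    expect_equal(sort(c(tk$retained, tk$removed)), sort(x))
    # retained preserves input order
    expect_equal(tk$retained, x[x >= tk$fences[1] & x <= tk$fences[2]])
    again <- tukey_filter(tk$retained, cfg)
    # values already inside their own fences stay put on data with no
    # removals; on filtered data a second pass can only shrink further
    expect_true(length(again$retained) <= length(tk$retained))
    if (length(tk$removed) == 0)
      expect_equal(again$retained, tk$retained)
  }
})

test_that("Hodges-Lehmann matches the worked Walsh-average examples", {
  expect_equal(hodges_lehmann(2), 2)
  expect_equal(hodges_lehmann(c(1, 2, 3)), 2)
  expect_equal(hodges_lehmann(c(0, 1, 2, 10)), 1.75)
  expect_error(hodges_lehmann(numeric(0)), "empty")
})

test_that("Hodges-Lehmann equals the enumeration oracle and is equivariant", {
  set.seed(505)
  for (rep in 1:200) {
    x <- round(runif(sample(1:9, 1), 0, 30), 1)
    expect_equal(hodges_lehmann(x), hl_oracle(x))
    a <- runif(1, 0.1, 3); b <- runif(1, -10, 10)
    expect_equal(hodges_lehmann(a * x), a * hodges_lehmann(x))
    expect_equal(hodges_lehmann(x + b), hodges_lehmann(x) + b)
    expect_gte(hodges_lehmann(x), min(x))
    expect_lte(hodges_lehmann(x), max(x))
  }
})

test_that("the per-bin pipeline composes midpoints, dedupe, Tukey, HL", {
  # symmetric midpoints, no outliers
  rec <- make_records(paleolat = rep(12, 3),
                      t_min = c(9, 11, 13), t_max = c(11, 13, 15))
  est <- estimate_bin(rec)
  expect_equal(est$hlm, 12)
  expect_equal(est$n, 3)
  expect_equal(est$n_int, 3)
  expect_equal(est$bin_label, 10)

  # outlier removed before HL: hlm = HL({1,2,3,4}) = 2.5
  rec2 <- make_records(paleolat = rep(12, 5),
                       t_min = c(0, 1, 2, 3, 99), t_max = c(2, 3, 4, 5, 101))
  est2 <- suppressWarnings(estimate_bin(rec2))
  expect_equal(est2$n_outliers_removed, 1)
  expect_equal(est2$hlm, 2.5)
  # quartiles/IQR reported from the pre-Tukey values that set the fences
  expect_equal(est2$q1, 2)
  expect_equal(est2$q3, 4)
  expect_equal(est2$iqr, 2)
  expect_false(est2$low_confidence)   # n = 5 meets the default minimum
  est3 <- estimate_bin(rec2[1:3, ])
  expect_true(est3$low_confidence)    # n = 3 falls below it
})

test_that("duplicate records change n but not n_int, hlm, or quartiles", {
  rec <- make_records(paleolat = rep(22, 4),
                      t_min = c(14, 16, 18, 20), t_max = c(18, 20, 22, 24))
  est <- estimate_bin(rec)
  dup <- rbind(rec, rec[c(1, 1, 3), ])
  est_dup <- estimate_bin(dup)
  expect_equal(est_dup$n, 7)
  expect_equal(est_dup$n_int, est$n_int)
  expect_equal(est_dup$hlm, est$hlm)
  expect_equal(est_dup$q1, est$q1)
  expect_equal(est_dup$q3, est$q3)
  # weighted mode, by contrast, does feel the multiplicities
  est_w <- estimate_bin(dup, estimator_config(dedupe_mode = "weighted"))
  expect_equal(est_w$n_int, est$n_int)
  expect_false(isTRUE(all.equal(est_w$hlm, est$hlm)))
})

test_that("bin estimation is invariant to record order", {
  set.seed(606)
  lat <- runif(30, 18, 22)
  tmin <- runif(30, 14, 20)
  rec <- make_records(paleolat = lat, t_min = tmin, t_max = tmin + 3)
  a <- estimate_bin(rec)
  b <- estimate_bin(rec[sample(30), ])
  expect_identical(a, b)
})

test_that("stage trends order bins and flag structure correctly", {
  rec <- make_records(paleolat = c(31, 12, 22, 13, 23),
                      t_min = c(15, 20, 18, 21, 17),
                      t_max = c(18, 23, 21, 24, 20))
  tr <- estimate_stage(rec, "Pragian")
  expect_s3_class(tr, "latitudinal_trend")
  expect_equal(tr$estimates$bin_label, c(10, 20, 30))
  expect_equal(nrow(tr$trend_points), 3)
  expect_true(all(diff(tr$trend_points$bin_label) > 0))

  # single-bin stage: a one-point trend
  tr1 <- estimate_stage(rec[rec$paleolat < 15, ], "Pragian")
  expect_equal(nrow(tr1$trend_points), 1)

  # empty stage: warning and empty trend
  expect_warning(tr0 <- estimate_stage(rec, "Induan"), "no admitted records")
  expect_equal(nrow(tr0$estimates), 0)
})

test_that("stage series averages bin HLMs and brackets the midpoints", {
  rec <- rbind(
    make_records(stage = "Pragian", paleolat = c(12, 12, 22, 22),
                 t_min = c(11, 11, 13, 13), t_max = c(13, 13, 15, 15)),
    make_records(stage = "Emsian", paleolat = c(12, 12, 22, 22),
                 t_min = c(19, 19, 21, 21), t_max = c(21, 21, 23, 23))
  )
  rec$record_id <- sprintf("r%03d", seq_len(nrow(rec)))
  ss <- stage_series(rec)
  # ordered by stage-chart age: Pragian (older) before Emsian
  expect_equal(ss$stage, c("Pragian", "Emsian"))
  expect_equal(ss$mean_hlm, c(13, 21))    # mean of bin HLMs {12, 14}, {20, 22}
  expect_true(all(ss$t_min <= ss$mean_hlm & ss$mean_hlm <= ss$t_max))
  expect_equal(ss$n_records, c(4, 4))
})
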