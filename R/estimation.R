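#' Estimator configuration
#'
#' Parameters of the per-bin temperature estimator. Records are grouped into
#' paleolatitudinal bins of `bin_width` degrees centred on multiples of the
#' width; identical thermal intervals are collapsed before estimation
#' (`dedupe_mode = "unique"`, so a taxon reported many times does not
#' dominate a bin) or counted with multiplicity (`"weighted"`). Outliers are
#' removed in a single pass outside the Tukey fences `[Q1 - k IQR,
#' Q3 + k IQR]` and the location is the Hodges-Lehmann pseudo-median of what
#' remains.
#'
#' @param bin_width Bin width in degrees of paleolatitude (default 10).
#' @param tukey_k Fence multiplier k (default 1.5).
#' @param quartile_method Quartile convention: `"interp_orderstat"` (linear
#'   interpolation of the sorted values at position `p (m - 1)`; R type 7,
#'   the default), `"inclusive"` (Tukey hinges), `"exclusive"` (R type 6).
#' @param dedupe_mode `"unique"` (default) or `"weighted"`.
#' @param min_bin_n Bins with fewer records than this are flagged
#'   low-confidence (default 5).
#' @return A list with class `"estimator_config"`.
#' @export
estimator_config <- function(bin_width = 10, tukey_k = 1.5,
                             quartile_method = c("interp_orderstat",
                                                 "inclusive", "exclusive"),
                             dedupe_mode = c("unique", "weighted"),
                             min_bin_n = 5) {
  stopifnot(bin_width > 0, tukey_k > 0, min_bin_n >= 0)
  structure(list(bin_width = bin_width, tukey_k = tukey_k,
                 quartile_method = match.arg(quartile_method),
                 dedupe_mode = match.arg(dedupe_mode),
                 min_bin_n = min_bin_n),
            class = "estimator_config")
}

#' Assign paleolatitudes to bins
#'
#' Bin labels are the nearest multiples of the bin width; each bin spans
#' `[label - width/2, label + width/2)`, so a value exactly on a boundary
#' goes to the higher-labelled bin. Hemispheres are never merged: the sign
#' of the latitude is preserved in the label.
#'
#' @param paleolat Numeric vector of paleolatitudes, degrees, |lat| <= 90.
#' @param cfg An [estimator_config()].
#' @return Numeric vector of bin labels.
#' @examples
#' assign_bin(c(23.4, 25, -12))  # 20, 30, -10
#' @export
assign_bin <- function(paleolat, cfg = estimator_config()) {
  stopifnot(all(abs(paleolat) <= 90, na.rm = TRUE))
  w <- cfg$bin_width
  floor(paleolat / w + 0.5) * w
}

#' Collapse identical temperature intervals
#'
#' Taxa with identical thermal tolerances carry no independent temperature
#' information, so records sharing one (stage, bin) are collapsed to unique
#' `(t_min, t_max)` pairs, compared after rounding to 0.01 degrees C (to
#' absorb text-parsing noise). Multiplicities sum to the record count; the
#' output is sorted by interval midpoint.
#'
#' @param records Occurrence data.frame (rows assumed to share one stage and
#'   bin), or any data.frame with `t_min_c`, `t_max_c`.
#' @return Data.frame `t_min_c`, `t_max_c`, `midpoint`, `multiplicity`.
#' @export
dedupe_intervals <- function(records) {
  lo <- round(records$t_min_c, 2)
  hi <- round(records$t_max_c, 2)
  key <- paste(lo, hi, sep = "|")
  agg <- table(key)
  first <- !duplicated(key)
  out <- data.frame(t_min_c = lo[first], t_max_c = hi[first],
                    stringsAsFactors = FALSE)
  out$midpoint <- (out$t_min_c + out$t_max_c) / 2
  out$multiplicity <- as.integer(agg[paste(out$t_min_c, out$t_max_c, sep = "|")])
  ord <- order(out$midpoint, out$t_min_c)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quartiles under a selectable convention
#'
#' @param values Non-empty numeric vector.
#' @param cfg An [estimator_config()]; `cfg$quartile_method` selects the
#'   convention (see there).
#' @return Named numeric vector `c(q1 = ..., q3 = ...)`.
#' @examples
#' quartiles(c(1, 2, 3, 4, 5))   # 2, 4
#' @export
quartiles <- function(values, cfg = estimator_config()) {
  if (length(values) == 0) stop("quartiles of an empty set")
  q <- switch(cfg$quartile_method,
    interp_orderstat = stats::quantile(values, c(0.25, 0.75), type = 7,
                                       names = FALSE),
    inclusive = stats::fivenum(values)[c(2, 4)],
    exclusive = stats::quantile(values, c(0.25, 0.75), type = 6,
                                names = FALSE)
  )
  c(q1 = q[1], q3 = q[2])
}

#' Tukey fence outlier removal
#'
#' A single (non-iterated) pass: values outside `[Q1 - k IQR, Q3 + k IQR]`
#' are removed, with inclusive fences, so constant data are never touched.
#' Retained values preserve the input order and retained plus removed
#' reconstitute the input as multisets.
#'
#' @param values Non-empty numeric vector.
#' @param cfg An [estimator_config()] supplying `tukey_k` and the quartile
#'   convention.
#' @return A list: `retained`, `removed`, `fences` (length-2 numeric).
#' @examples
#' tukey_filter(c(1, 2, 3, 4, 100))$removed   # 100
#' @export
tukey_filter <- function(values, cfg = estimator_config()) {
  if (length(values) == 0) stop("tukey_filter of an empty set")
  q <- quartiles(values, cfg)
  iqr <- q["q3"] - q["q1"]
  fences <- unname(c(q["q1"] - cfg$tukey_k * iqr, q["q3"] + cfg$tukey_k * iqr))
  inside <- values >= fences[1] & values <= fences[2]
  list(retained = values[inside], removed = values[!inside], fences = fences)
}

#' Hodges-Lehmann pseudo-median
#'
#' The median of all Walsh averages `(x_i + x_j) / 2` over pairs `i <= j`
#' (self-pairs included): a robust location estimate suited to the skewed,
#' non-normal temperature distributions that assemblages of mixed taxa
#' produce. The median of an even number of Walsh averages is the mean of
#' the two central order statistics.
#'
#' @param values Non-empty numeric vector.
#' @return The pseudo-median, a single numeric value.
#' @examples
#' hodges_lehmann(c(0, 1, 2, 10))  # 1.75
#' @export
hodges_lehmann <- function(values) {
  n <- length(values)
  if (n == 0) stop("hodges_lehmann of an empty set")
  if (n == 1) return(as.numeric(values))
  w <- outer(values, values, "+") / 2
  stats::median(w[upper.tri(w, diag = TRUE)])
}

#' Estimate the temperature of one (stage, bin) cell
#'
#' The per-bin pipeline: interval midpoints, deduplication of identical
#' intervals, quartiles and IQR of the (pre-outlier-removal) value set,
#' Tukey fence filtering, and the Hodges-Lehmann pseudo-median of the
#' retained values. `n` counts records entering the bin, `n_int` the unique
#' thermal intervals, both before outlier removal; `q1`/`q3`/`iqr` are
#' reported from the pre-Tukey values so the published IQR is the one that
#' defined the fences.
#'
#' @param records_in_bin Occurrence data.frame sharing one (stage, bin);
#'   must be non-empty.
#' @param cfg An [estimator_config()].
#' @param stage,bin_label Optional labels; inferred from the records when
#'   missing.
#' @return One-row data.frame: `stage`, `bin_label`, `n`, `n_int`, `hlm`,
#'   `q1`, `q3`, `iqr`, `n_outliers_removed`, `low_confidence`.
#' @export
estimate_bin <- function(records_in_bin, cfg = estimator_config(),
                         stage = NULL, bin_label = NULL) {
  if (is.null(records_in_bin) || nrow(records_in_bin) == 0)
    stop("estimate_bin on an empty bin")
  if (is.null(stage)) stage <- records_in_bin$stage[1]
  if (is.null(bin_label))
    bin_label <- assign_bin(records_in_bin$paleolat[1], cfg)
  dd <- dedupe_intervals(records_in_bin)
  values <- switch(cfg$dedupe_mode,
    unique = dd$midpoint,
    weighted = rep(dd$midpoint, dd$multiplicity)
  )
  q <- quartiles(values, cfg)
  tk <- tukey_filter(values, cfg)
  data.frame(
    stage = stage, bin_label = bin_label,
    n = nrow(records_in_bin), n_int = nrow(dd),
    hlm = hodges_lehmann(tk$retained),
    q1 = unname(q["q1"]), q3 = unname(q["q3"]),
    iqr = unname(q["q3"] - q["q1"]),
    n_outliers_removed = length(tk$removed),
    low_confidence = nrow(records_in_bin) < cfg$min_bin_n,
    stringsAsFactors = FALSE
  )
}

#' Latitudinal temperature trend of one stage
#'
#' Groups a stage's screened records into paleolatitudinal bins, estimates
#' each occupied bin with [estimate_bin()], and returns the estimates ordered
#' by bin label together with the piecewise-linear trend through the
#' (bin label, HLM) points.
#'
#' @param records Screened occurrence data.frame (may span several stages).
#' @param stage Stage name to extract.
#' @param cfg An [estimator_config()].
#' @return A list of class `"latitudinal_trend"`: `stage`, `estimates`
#'   (data.frame, one row per occupied bin), `trend_points` (data.frame
#'   `bin_label`, `hlm`).
#' @export
estimate_stage <- function(records, stage, cfg = estimator_config()) {
  sub <- records[records$stage == stage, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no admitted records for stage ", stage)
    est <- data.frame(stage = character(), bin_label = numeric(),
                      n = integer(), n_int = integer(), hlm = numeric(),
                      q1 = numeric(), q3 = numeric(), iqr = numeric(),
                      n_outliers_removed = integer(),
                      low_confidence = logical(), stringsAsFactors = FALSE)
    return(structure(list(stage = stage, estimates = est,
                          trend_points = est[, c("bin_label", "hlm")]),
                     class = "latitudinal_trend"))
  }
  bins <- assign_bin(sub$paleolat, cfg)
  labs <- sort(unique(bins))
  est <- do.call(rbind, lapply(labs, function(b) {
    estimate_bin(sub[bins == b, , drop = FALSE], cfg, stage = stage,
                 bin_label = b)
  }))
  rownames(est) <- NULL
  structure(list(stage = stage, estimates = est,
                 trend_points = est[, c("bin_label", "hlm")]),
            class = "latitudinal_trend")
}

#' @export
print.latitudinal_trend <- function(x, ...) {
  cat("Latitudinal temperature trend --", x$stage, "\n")
  print(x$estimates[, c("bin_label", "n", "n_int", "hlm", "q1", "q3", "iqr")],
        row.names = FALSE)
  invisible(x)
}

#' Stage-by-stage temperature series
#'
#' Per stage: the unweighted mean of the bin HLM estimates, the minimum and
#' maximum of the admitted record midpoints, and the record count. Stages
#' are ordered by the [stage_table()] ages (oldest first); stages without
#' records are absent.
#'
#' @param records Screened occurrence data.frame.
#' @param cfg An [estimator_config()].
#' @return Data.frame `stage`, `mean_hlm`, `t_min`, `t_max`, `n_records`.
#' @export
stage_series <- function(records, cfg = estimator_config()) {
  stages_present <- unique(records$stage)
  st <- stage_table()
  ordered <- c(st$stage[st$stage %in% stages_present],
               setdiff(stages_present, st$stage))
  rows <- lapply(ordered, function(s) {
    tr <- estimate_stage(records, s, cfg)
    mids <- midpoint(records[records$stage == s, , drop = FALSE])
    data.frame(stage = s, mean_hlm = mean(tr$estimates$hlm),
               t_min = min(mids), t_max = max(mids),
               n_records = sum(records$stage == s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
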