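#' Fit biotic paleotemperature estimates to an occurrence dataset
#'
#' The package's central fitting function. Occurrence records are screened
#' (tolerance width, bathymetry, and -- when a [grade_spec()] is supplied --
#' the exotic-migrant exclusion), grouped into paleolatitudinal bins per
#' stage, and each occupied (stage, bin) cell is summarised by the robust
#' pipeline of [estimate_bin()]: interval midpoints, deduplication of
#' identical thermal intervals, Tukey-fence outlier removal, and the
#' Hodges-Lehmann pseudo-median.
#'
#' @param records Occurrence data.frame in the flat format of
#'   [occurrence_fields()] (e.g. from [read_occurrences()] or
#'   [generate_dataset()]).
#' @param screening A [screening_config()].
#' @param estimator An [estimator_config()].
#' @param grades Optional [grade_spec()] driving the overlap exclusion.
#' @param stages Stages to fit; default all stages present in the data,
#'   ordered by [stage_table()] age.
#' @return An object of class `"paleotherm"`: a list with components
#'   `estimates` (data.frame of per-(stage, bin) rows), `trends` (named list
#'   of [estimate_stage()] results), `series` (the [stage_series()] frame),
#'   `report` (screening report), `records` (admitted records), `excluded_taxa`,
#'   `screening`, `estimator`, `call`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' gen <- generate_dataset(synthetic_spec(seed = 1, n_taxa = 40))
#' fit <- paleotherm(gen$records)
#' coef(fit)
#' predict(fit, data.frame(stage = "Pragian", paleolat = 23))
#' @export
paleotherm <- function(records, screening = screening_config(),
                       estimator = estimator_config(), grades = NULL,
                       stages = NULL) {
  scr <- screen_records(records, screening, grades)
  kept <- scr$records
  if (is.null(stages)) {
    present <- unique(kept$stage)
    st <- stage_table()$stage
    stages <- c(st[st %in% present], setdiff(present, st))
  }
  trends <- lapply(stages, function(s) estimate_stage(kept, s, estimator))
  names(trends) <- stages
  estimates <- do.call(rbind, lapply(trends, `[[`, "estimates"))
  rownames(estimates) <- NULL
  series <- if (nrow(kept)) stage_series(kept, estimator) else NULL
  structure(list(estimates = estimates, trends = trends, series = series,
                 report = scr$report, records = kept,
                 excluded_taxa = scr$excluded_taxa,
                 screening = screening, estimator = estimator,
                 call = match.call()),
            class = "paleotherm")
}

#' @export
print.paleotherm <- function(x, ...) {
  cat("Biotic paleotemperature fit\n")
  cat(sprintf("  %d admitted records of %d input (%d stage(s), %d (stage, bin) cells)\n",
              x$report$n_retained, x$report$n_input,
              length(x$trends), nrow(x$estimates)))
  if (!is.null(x$estimates) && nrow(x$estimates))
    print(x$estimates[, c("stage", "bin_label", "n", "n_int", "hlm",
                          "q1", "q3", "iqr")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.paleotherm <- function(object, ...) {
  structure(list(fit = object), class = "summary.paleotherm")
}

#' @export
print.summary.paleotherm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n")
  print(f$report)
  if (!is.null(f$series)) {
    cat("\nStage series (mean of bin HLMs, range of admitted midpoints):\n")
    print(f$series, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.paleotherm <- function(object, ...) {
  e <- object$estimates
  if (is.null(e) || nrow(e) == 0) return(numeric())
  stats::setNames(e$hlm, paste(e$stage, e$bin_label, sep = ":"))
}

#' Predict temperatures along the fitted latitudinal trends
#'
#' Piecewise-linear interpolation of the (bin label, HLM) trend points of
#' each stage; latitudes outside the occupied bins are clamped to the
#' nearest end of the trend. Single-bin stages predict that bin's constant.
#'
#' @param object A [paleotherm()] fit.
#' @param newdata Data.frame with columns `stage` and `paleolat`. Defaults
#'   to the admitted records.
#' @param ... Unused.
#' @return Numeric vector of temperatures (degrees C), `NA` for stages not
#'   in the fit.
#' @export
predict.paleotherm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- object$records[, c("stage", "paleolat"), drop = FALSE]
  out <- rep(NA_real_, nrow(newdata))
  for (s in unique(newdata$stage)) {
    tr <- object$trends[[s]]
    if (is.null(tr) || nrow(tr$trend_points) == 0) next
    i <- newdata$stage == s
    tp <- tr$trend_points
    if (nrow(tp) == 1) out[i] <- tp$hlm
    else out[i] <- stats::approx(tp$bin_label, tp$hlm,
                                 xout = newdata$paleolat[i], rule = 2)$y
  }
  out
}

#' @export
fitted.paleotherm <- function(object, ...) {
  predict(object)
}

#' @export
residuals.paleotherm <- function(object, ...) {
  midpoint(object$records) - fitted(object)
}

#' Plot a fitted latitudinal trend
#'
#' Record midpoints against paleolatitude for one stage, with the
#' Hodges-Lehmann trend line through the bin estimates drawn in red.
#'
#' @param x A [paleotherm()] fit.
#' @param stage Stage to plot (default the first fitted stage).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.paleotherm <- function(x, stage = NULL, ...) {
  if (is.null(stage)) stage <- names(x$trends)[1]
  rec <- x$records[x$records$stage == stage, , drop = FALSE]
  tr <- x$trends[[stage]]
  graphics::plot(rec$paleolat, midpoint(rec),
                 xlab = "paleolatitude (deg)",
                 ylab = "interval midpoint (deg C)",
                 main = paste("Biotic paleotemperatures --", stage),
                 col = grDevices::grey(0.45), pch = 16, cex = 0.6, ...)
  if (nrow(tr$trend_points) > 1)
    graphics::lines(tr$trend_points$bin_label, tr$trend_points$hlm,
                    col = "red", lwd = 2)
  graphics::points(tr$trend_points$bin_label, tr$trend_points$hlm,
                   col = "red", pch = 19)
  invisible(x)
}
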