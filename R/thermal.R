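#' Thermal tolerance ranges
#'
#' A thermal range is the habitat-temperature interval `[t_min, t_max]` (in
#' degrees Celsius) attached to a taxon: the span of mean temperatures under
#' which the taxon is inferred to live. Its width gauges how informative the
#' taxon is as a temperature proxy, and its midpoint is the single temperature
#' value each occurrence record contributes to the estimator.
#'
#' `thermal_range()` validates and returns the pair; bounds outside the
#' plausible marine envelope of -5 to 45 degrees C trigger a warning but are
#' kept (the caller may be working with unusual settings).
#'
#' @param t_min,t_max Numeric vectors, lower and upper habitat temperature in
#'   degrees C. Recycled to a common length.
#' @return For `thermal_range()`, a data.frame with columns `t_min`, `t_max`.
#'   For `tolerance_width()` and `midpoint()`, a numeric vector.
#' @examples
#' thermal_range(18, 25)
#' tolerance_width(18, 25)   # 7
#' midpoint(18, 25)          # 21.5
#' @export
thermal_range <- function(t_min, t_max) {
  n <- max(length(t_min), length(t_max))
  t_min <- rep_len(as.numeric(t_min), n)
  t_max <- rep_len(as.numeric(t_max), n)
  if (any(!is.finite(t_min)) || any(!is.finite(t_max)))
    stop("thermal range bounds must be finite")
  if (any(t_min > t_max))
    stop("thermal range has t_min > t_max")
  if (any(t_min < -5 | t_max > 45))
    warning("thermal range outside the plausible -5..45 degrees C envelope")
  data.frame(t_min = t_min, t_max = t_max)
}

#' @param thermal Optionally, a data.frame with columns `t_min`/`t_max` (or
#'   `t_min_c`/`t_max_c`) in place of the two numeric arguments.
#' @rdname thermal_range
#' @export
tolerance_width <- function(t_min, t_max = NULL, thermal = NULL) {
  b <- .thermal_bounds(t_min, t_max, thermal)
  b$t_max - b$t_min
}

#' @rdname thermal_range
#' @export
midpoint <- function(t_min, t_max = NULL, thermal = NULL) {
  b <- .thermal_bounds(t_min, t_max, thermal)
  (b$t_min + b$t_max) / 2
}

# accept (t_min, t_max) vectors or a records-like data.frame
.thermal_bounds <- function(t_min, t_max, thermal) {
  if (!is.null(thermal)) t_min <- thermal
  if (is.data.frame(t_min)) {
    df <- t_min
    lo <- if ("t_min" %in% names(df)) df$t_min else df$t_min_c
    hi <- if ("t_max" %in% names(df)) df$t_max else df$t_max_c
    if (is.null(lo) || is.null(hi))
      stop("data.frame input needs t_min/t_max or t_min_c/t_max_c columns")
    return(list(t_min = as.numeric(lo), t_max = as.numeric(hi)))
  }
  list(t_min = as.numeric(t_min), t_max = as.numeric(t_max))
}
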