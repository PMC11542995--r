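#' Screening configuration
#'
#' Parameters of the ecological filters deciding which occurrence records are
#' admissible sea-surface temperature evidence. Taxa with tolerance widths up
#' to `narrow_cutoff` are "narrow" (stenothermal, most informative); widths up
#' to `max_tolerance_width` are "moderate"; wider taxa carry too little
#' temperature information and are excluded. Deep-water records (habitat
#' below `deep_cutoff_m`) reflect permanently cold bottom water rather than
#' surface temperature and are excluded when `exclude_deep` is set. Taxa
#' whose thermal range belongs to both a warm and a cold grade set (exotic,
#' wide-ranging migrants) are excluded when `exclude_overlap` is set.
#'
#' @param max_tolerance_width Admissibility bound on `t_max - t_min`,
#'   degrees C, inclusive (default 5).
#' @param narrow_cutoff Narrow/moderate boundary, degrees C, inclusive
#'   (default 3).
#' @param deep_cutoff_m Depth (m) beyond which a habitat counts as deep
#'   water; convention 250-300 m, default 300.
#' @param exclude_deep,exclude_overlap Logical switches (default `TRUE`).
#' @return A list with class `"screening_config"`.
#' @export
screening_config <- function(max_tolerance_width = 5.0, narrow_cutoff = 3.0,
                             deep_cutoff_m = 300, exclude_deep = TRUE,
                             exclude_overlap = TRUE) {
  stopifnot(narrow_cutoff > 0, narrow_cutoff < max_tolerance_width,
            deep_cutoff_m > 0)
  structure(list(max_tolerance_width = max_tolerance_width,
                 narrow_cutoff = narrow_cutoff,
                 deep_cutoff_m = deep_cutoff_m,
                 exclude_deep = isTRUE(exclude_deep),
                 exclude_overlap = isTRUE(exclude_overlap)),
            class = "screening_config")
}

#' Classify a thermal-tolerance width
#'
#' Boundary semantics are inclusive on both cutoffs: a width exactly equal to
#' `narrow_cutoff` is `"narrow"`, exactly `max_tolerance_width` is
#' `"moderate"`; anything wider is `"excluded"`.
#'
#' @param width Numeric vector of tolerance widths (degrees C), e.g. from
#'   [tolerance_width()].
#' @param cfg A [screening_config()].
#' @return Character vector in `{"narrow", "moderate", "excluded"}`.
#' @examples
#' classify_tolerance(c(2.5, 4, 6), screening_config())
#' @export
classify_tolerance <- function(width, cfg = screening_config()) {
  ifelse(width <= cfg$narrow_cutoff, "narrow",
         ifelse(width <= cfg$max_tolerance_width, "moderate", "excluded"))
}

.empty_report <- function() {
  structure(list(
    n_input = 0L, n_retained = 0L, n_after_tolerance = 0L,
    n_narrow = 0L, n_moderate = 0L, n_wide_excluded = 0L,
    n_deepwater_excluded = 0L, n_overlap_excluded = 0L, n_unknown_depth = 0L,
    n_taxa_input = 0L, n_taxa_deep_excluded = 0L, n_taxa_overlap_excluded = 0L,
    n_collections_input = 0L, n_collections_deep = 0L,
    fractions = list()
  ), class = "screening_report")
}

.report_fractions <- function(r) {
  den <- function(x, d) if (d > 0) x / d else 0
  r$fractions <- list(
    narrow = den(r$n_narrow, r$n_input),
    moderate = den(r$n_moderate, r$n_input),
    wide_excluded = den(r$n_wide_excluded, r$n_input),
    deepwater_excluded = den(r$n_deepwater_excluded, r$n_input),
    overlap_excluded = den(r$n_overlap_excluded, r$n_input),
    retained = den(r$n_retained, r$n_input),
    taxa_deep_excluded = den(r$n_taxa_deep_excluded, r$n_taxa_input),
    taxa_overlap_excluded = den(r$n_taxa_overlap_excluded, r$n_taxa_input),
    collections_deep = den(r$n_collections_deep, r$n_collections_input)
  )
  r
}

#' Apply the admissibility filters
#'
#' Removes records failing the tolerance-width rule, then (when
#' `cfg$exclude_deep`) deep-water records; records with unknown depth are
#' retained with a warning, since only habitats known to be exclusively deep
#' disqualify a record as surface-temperature evidence. Order of retained
#' records is preserved, and the report tallies every rule's removals at both
#' the record and the taxon/collection level (the two denominators over which
#' deep-water prevalence can be quoted).
#'
#' @param records Validated occurrence data.frame.
#' @param cfg A [screening_config()].
#' @return A list: `records` (retained rows) and `report` (a
#'   `screening_report`; see [print.screening_report()]).
#' @export
filter_admissible <- function(records, cfg = screening_config()) {
  r <- .empty_report()
  if (is.null(records) || nrow(records) == 0)
    return(list(records = records[0, , drop = FALSE], report = .report_fractions(r)))

  width <- tolerance_width(records)
  cls <- classify_tolerance(width, cfg)
  tol_ok <- cls != "excluded"
  deep <- records$depth_class == "deep"
  drop_deep <- cfg$exclude_deep & deep & tol_ok
  keep <- tol_ok & !drop_deep

  r$n_input <- nrow(records)
  r$n_wide_excluded <- sum(!tol_ok)
  r$n_deepwater_excluded <- sum(drop_deep)
  r$n_narrow <- sum(cls == "narrow" & keep)
  r$n_moderate <- sum(cls == "moderate" & keep)
  r$n_after_tolerance <- r$n_narrow + r$n_moderate
  r$n_retained <- sum(keep)
  r$n_unknown_depth <- sum(records$depth_class == "unknown" & keep)
  if (r$n_unknown_depth > 0)
    warning(r$n_unknown_depth,
            " record(s) with unknown depth class retained as surface evidence")

  taxa <- unique(records$taxon_name)
  r$n_taxa_input <- length(taxa)
  # taxa found exclusively in deep water
  deep_only <- vapply(split(deep, records$taxon_name), all, logical(1))
  r$n_taxa_deep_excluded <- if (cfg$exclude_deep) sum(deep_only) else 0L
  r$n_collections_input <- length(unique(records$collection_id))
  col_deep <- vapply(split(deep, records$collection_id), all, logical(1))
  r$n_collections_deep <- sum(col_deep)

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = .report_fractions(r))
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat(sprintf("  records in:            %d\n", x$n_input))
  cat(sprintf("  retained:              %d (narrow %d, moderate %d)\n",
              x$n_retained, x$n_narrow, x$n_moderate))
  cat(sprintf("  wide tolerance (>%s C) excluded: %d\n",
              "max", x$n_wide_excluded))
  cat(sprintf("  deep-water excluded:   %d records (%d taxa exclusively deep)\n",
              x$n_deepwater_excluded, x$n_taxa_deep_excluded))
  cat(sprintf("  overlap excluded:      %d records (%d taxa)\n",
              x$n_overlap_excluded, x$n_taxa_overlap_excluded))
  invisible(x)
}

#' Warm/cold grade specification
#'
#' Two independent temperature sample sets -- a warm ("red") and a cold
#' ("blue") range -- against which taxa are classified. The ranges may
#' overlap; the overlap region is what drives the exotic-taxon exclusion
#' rule. Three membership rules are available: `"midpoint"` (the thermal
#' range's midpoint falls in the set), `"containment"` (the whole range lies
#' inside the set), `"overlap"` (the range intersects the set).
#'
#' @param red,blue Length-2 numeric `(t_min, t_max)` in degrees C, or a
#'   one-row data.frame from [thermal_range()].
#' @param membership_rule One of `"midpoint"` (default), `"containment"`,
#'   `"overlap"`.
#' @return A list with class `"grade_spec"`.
#' @export
grade_spec <- function(red, blue, membership_rule = c("midpoint", "containment",
                                                      "overlap")) {
  as_rng <- function(x) {
    if (is.data.frame(x)) x <- c(x$t_min[1], x$t_max[1])
    x <- as.numeric(x)
    stopifnot(length(x) == 2, is.finite(x), x[1] <= x[2])
    x
  }
  structure(list(red = as_rng(red), blue = as_rng(blue),
                 membership_rule = match.arg(membership_rule)),
            class = "grade_spec")
}

#' Classify records against warm/cold grades
#'
#' @param t_min,t_max Numeric vectors of thermal-range bounds, or a records
#'   data.frame as the first argument.
#' @param spec A [grade_spec()].
#' @return Character vector in `{"red", "blue", "both", "neither"}`. Under
#'   the midpoint rule `"both"` occurs only when the midpoint lies in the
#'   intersection of the two ranges.
#' @examples
#' gs <- grade_spec(red = c(18, 35), blue = c(0, 10))
#' classify_grade(19, 23, gs)  # "red"
#' @export
classify_grade <- function(t_min, t_max = NULL, spec) {
  b <- .thermal_bounds(t_min, t_max, NULL)
  in_set <- switch(spec$membership_rule,
    midpoint = function(rng) {
      m <- (b$t_min + b$t_max) / 2
      m >= rng[1] & m <= rng[2]
    },
    containment = function(rng) b$t_min >= rng[1] & b$t_max <= rng[2],
    overlap = function(rng) b$t_min <= rng[2] & b$t_max >= rng[1]
  )
  r <- in_set(spec$red); bl <- in_set(spec$blue)
  ifelse(r & bl, "both", ifelse(r, "red", ifelse(bl, "blue", "neither")))
}

#' Exclude taxa overlapping both grades
#'
#' Implements the exotic-migrant rule: taxa whose thermal range is classified
#' `"both"` against the grade spec conflict between the warm and cold sets
#' (wide-ranging or out-of-zone migrants) and all their records are removed.
#' Operates at taxon level because the exclusion is about a taxon's habit,
#' not an individual find. A no-op when `cfg$exclude_overlap` is `FALSE`.
#'
#' @param records Screened occurrence data.frame.
#' @param spec A [grade_spec()].
#' @param cfg A [screening_config()].
#' @return A list: `records` (retained), `excluded_taxa` (data.frame
#'   `taxon_name`, `t_min_c`, `t_max_c`).
#' @export
exclude_overlapping <- function(records, spec, cfg = screening_config()) {
  empty <- data.frame(taxon_name = character(), t_min_c = numeric(),
                      t_max_c = numeric(), stringsAsFactors = FALSE)
  if (!cfg$exclude_overlap || is.null(records) || nrow(records) == 0)
    return(list(records = records, excluded_taxa = empty))
  g <- classify_grade(records, spec = spec)
  bad_taxa <- unique(records$taxon_name[g == "both"])
  if (!length(bad_taxa))
    return(list(records = records, excluded_taxa = empty))
  drop <- records$taxon_name %in% bad_taxa
  ex <- unique(records[drop, c("taxon_name", "t_min_c", "t_max_c")])
  rownames(ex) <- NULL
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, excluded_taxa = ex)
}

#' Full screening pass
#'
#' Composes [filter_admissible()] and, when a grade spec is supplied and
#' `cfg$exclude_overlap` is set, [exclude_overlapping()], folding the overlap
#' tallies into one screening report.
#'
#' @param records Validated occurrence data.frame.
#' @param cfg A [screening_config()].
#' @param grades Optional [grade_spec()] for the overlap rule.
#' @return A list: `records`, `report`, `excluded_taxa`.
#' @export
screen_records <- function(records, cfg = screening_config(), grades = NULL) {
  adm <- filter_admissible(records, cfg)
  report <- adm$report
  ex <- NULL
  out <- adm$records
  if (!is.null(grades) && cfg$exclude_overlap) {
    ov <- exclude_overlapping(out, grades, cfg)
    report$n_overlap_excluded <- nrow(out) - nrow(ov$records)
    report$n_taxa_overlap_excluded <- length(unique(ov$excluded_taxa$taxon_name))
    report$n_retained <- nrow(ov$records)
    report <- .report_fractions(report)
    out <- ov$records
    ex <- ov$excluded_taxa
  }
  list(records = out, report = report, excluded_taxa = ex)
}
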