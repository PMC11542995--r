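#' Synthetic dataset specification
#'
#' Describes a simulated occurrence dataset with the statistical structure
#' the estimator assumes: taxa with mostly narrow thermal tolerances, a
#' monotone latitudinal sea-surface temperature gradient, several records per
#' taxon (so record counts far exceed unique-interval counts), a minority of
#' deep-water-only taxa and a minority of exotic warm-water migrants at high
#' latitude. All randomness flows from `seed`; there is no implicit RNG use.
#'
#' Taxon temperatures are the gradient value at the taxon's home latitude
#' plus a noise term truncated at two standard deviations -- thermal niches
#' are modelled as bounded scatter around the local sea-surface temperature,
#' which also makes planted contamination exactly separable from the clean
#' taxa. Record paleolatitudes jitter around the home latitude by at most
#' 2 degrees.
#'
#' @param seed Integer seed (mandatory).
#' @param stages Character vector of stage names (default `"Pragian"`).
#' @param lat_range Length-2 degrees interval for taxon home latitudes
#'   (default `c(5, 45)`, spanning the 10-40 degree bins).
#' @param n_taxa Number of taxa (default 100).
#' @param records_per_taxon_mean Mean records per taxon per stage
#'   (default 7; every taxon gets at least one record).
#' @param gradient_intercept,gradient_slope Linear gradient
#'   `T(l) = intercept + slope * |l|` in degrees C (defaults 25 and -0.25).
#' @param tolerance_width_range Uniform bounds for tolerance widths,
#'   degrees C (default `c(1, 5)`).
#' @param frac_deepwater_taxa Fraction of taxa planted as deep-water only
#'   (default 0.09).
#' @param frac_exotic_taxa Fraction planted as exotic warm-water migrants
#'   (default 0.03).
#' @param exotic_offset Temperature shift of exotic taxa, degrees C
#'   (default +10).
#' @param noise_sd Standard deviation of the (truncated) taxon-level noise,
#'   degrees C (default 1).
#' @return A list with class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed, stages = "Pragian", lat_range = c(5, 45),
                           n_taxa = 100, records_per_taxon_mean = 7,
                           gradient_intercept = 25, gradient_slope = -0.25,
                           tolerance_width_range = c(1, 5),
                           frac_deepwater_taxa = 0.09,
                           frac_exotic_taxa = 0.03,
                           exotic_offset = 10, noise_sd = 1.0) {
  stopifnot(length(seed) == 1, is.finite(seed),
            length(lat_range) == 2, lat_range[1] < lat_range[2],
            n_taxa >= 0, records_per_taxon_mean >= 1,
            frac_deepwater_taxa >= 0, frac_deepwater_taxa <= 1,
            frac_exotic_taxa >= 0, frac_exotic_taxa <= 1,
            noise_sd >= 0, tolerance_width_range[1] > 0,
            tolerance_width_range[1] <= tolerance_width_range[2])
  structure(list(seed = as.integer(seed), stages = stages,
                 lat_range = lat_range, n_taxa = n_taxa,
                 records_per_taxon_mean = records_per_taxon_mean,
                 gradient_intercept = gradient_intercept,
                 gradient_slope = gradient_slope,
                 tolerance_width_range = tolerance_width_range,
                 frac_deepwater_taxa = frac_deepwater_taxa,
                 frac_exotic_taxa = frac_exotic_taxa,
                 exotic_offset = exotic_offset, noise_sd = noise_sd),
            class = "synthetic_spec")
}

.gradient <- function(spec, lat) {
  spec$gradient_intercept + spec$gradient_slope * abs(lat)
}

#' Generate a synthetic occurrence dataset
#'
#' Draws taxa along the latitudinal gradient of a [synthetic_spec()] and
#' scatters each across nearby collections. Exactly
#' `round(frac_deepwater_taxa * n_taxa)` taxa are planted deep-water-only and
#' `round(frac_exotic_taxa * n_taxa)` as exotic migrants (home latitudes in
#' the colder half of the range, thermal interval shifted warm by
#' `exotic_offset`); tolerance intervals are centred on the taxon temperature
#' with bounds rounded to 0.1 degrees C. Fully reproducible from the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `records` (flat occurrence data.frame), `truth`
#'   (data.frame `stage`, `bin_label`, `t_true`, the noise-free gradient at
#'   each bin centre), `planted` (list with `deep_taxa`, `exotic_taxa` name
#'   vectors).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ecfg <- estimator_config()
  empty <- utils::read.csv(text = paste(occurrence_fields(), collapse = ","),
                           stringsAsFactors = FALSE)
  if (spec$n_taxa == 0)
    return(list(records = empty,
                truth = data.frame(stage = character(), bin_label = numeric(),
                                   t_true = numeric()),
                planted = list(deep_taxa = character(),
                               exotic_taxa = character())))

  n <- spec$n_taxa
  n_deep <- round(spec$frac_deepwater_taxa * n)
  n_exotic <- round(spec$frac_exotic_taxa * n)
  taxon <- sprintf("Taxon_%04d", seq_len(n))
  role <- rep("clean", n)
  if (n_deep > 0) role[seq_len(n_deep)] <- "deep"
  if (n_exotic > 0) role[n_deep + seq_len(n_exotic)] <- "exotic"

  lo <- spec$lat_range[1]; hi <- spec$lat_range[2]
  home <- stats::runif(n, lo, hi)
  # exotic migrants live at high (cold) latitudes
  mid_lat <- (lo + hi) / 2
  home[role == "exotic"] <- stats::runif(n_exotic, mid_lat, hi)

  noise <- stats::rnorm(n, 0, spec$noise_sd)
  noise <- pmin(pmax(noise, -2 * spec$noise_sd), 2 * spec$noise_sd)
  t_taxon <- .gradient(spec, home) + noise
  t_taxon[role == "exotic"] <- t_taxon[role == "exotic"] + spec$exotic_offset
  w <- stats::runif(n, spec$tolerance_width_range[1],
                    spec$tolerance_width_range[2])
  t_min <- round(t_taxon - w / 2, 1)
  t_max <- round(t_taxon + w / 2, 1)

  subbasins <- c("Nordvik", "Kharaulakh", "Verkhoyansk", "Tunguska", "Vilyui")
  rows <- vector("list", length(spec$stages) * n)
  k <- 0L
  for (s in spec$stages) {
    n_rec <- 1L + stats::rpois(n, spec$records_per_taxon_mean - 1)
    for (i in seq_len(n)) {
      m <- n_rec[i]
      lat <- home[i] + stats::runif(m, -2, 2)
      lat <- pmin(pmax(lat, lo), hi - 1e-9)
      k <- k + 1L
      rows[[k]] <- data.frame(
        record_id = sprintf("%s_%s_r%02d", s, taxon[i], seq_len(m)),
        collection_id = sprintf("%s_%s_c%02d", s, taxon[i], seq_len(m)),
        taxon_name = taxon[i],
        gbif_id = 1000000L + i,
        rank = "genus",
        stage = s,
        subbasin = subbasins[1 + (i %% length(subbasins))],
        paleolat = lat,
        paleolon = stats::runif(m, 60, 120),
        lat_modern = lat + 25,
        lon_modern = stats::runif(m, 90, 130),
        depth_class = if (role[i] == "deep") "deep" else "shallow",
        t_min_c = t_min[i],
        t_max_c = t_max[i],
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows[seq_len(k)])
  rownames(records) <- NULL

  bins <- sort(unique(assign_bin(records$paleolat, ecfg)))
  truth <- do.call(rbind, lapply(spec$stages, function(s)
    data.frame(stage = s, bin_label = bins, t_true = .gradient(spec, bins),
               stringsAsFactors = FALSE)))
  list(records = records, truth = truth,
       planted = list(deep_taxa = taxon[role == "deep"],
                      exotic_taxa = taxon[role == "exotic"]))
}

#' Parameter-recovery experiment
#'
#' The end-to-end harness: generates a dataset, screens it (tolerance and
#' bathymetry rules, then the exotic-migrant exclusion), estimates every
#' (stage, bin), and compares the estimates with the planted noise-free
#' gradient. Migrants are detected per latitudinal bin with a [grade_spec()]
#' whose warm set starts half an `exotic_offset` above the local gradient
#' value (midpoint rule, cold set spanning the whole habitable range), so a
#' taxon that belongs to the regional set *and* the anomalously-warm set
#' classifies `"both"` and is excluded at taxon level -- a global warm/cold
#' split cannot separate migrants from warm-end locals once the latitudinal
#' span exceeds the offset.
#'
#' @param spec A [synthetic_spec()].
#' @param screening_cfg A [screening_config()].
#' @param estimator_cfg An [estimator_config()].
#' @return A list: `errors` (data.frame `stage`, `bin_label`, `t_true`,
#'   `hlm`, `abs_error`, `n`), `max_abs_error`, `report` (screening report),
#'   `excluded_taxa`, `records` (post-screening), `truth`, `planted`.
#' @export
recovery_experiment <- function(spec, screening_cfg = screening_config(),
                                estimator_cfg = estimator_config()) {
  gen <- generate_dataset(spec)
  adm <- filter_admissible(gen$records, screening_cfg)
  report <- adm$report
  kept <- adm$records
  excluded_taxa <- character()

  if (screening_cfg$exclude_overlap && nrow(kept)) {
    bins <- assign_bin(kept$paleolat, estimator_cfg)
    kept_parts <- split(kept, bins)
    drop_taxa <- unlist(lapply(names(kept_parts), function(b) {
      part <- kept_parts[[b]]
      boundary <- .gradient(spec, as.numeric(b)) + spec$exotic_offset / 2
      gs <- grade_spec(red = c(boundary, 60), blue = c(-10, 60),
                       membership_rule = "midpoint")
      ex <- exclude_overlapping(part, gs, screening_cfg)
      ex$excluded_taxa$taxon_name
    }))
    excluded_taxa <- unique(drop_taxa)
    drop <- kept$taxon_name %in% excluded_taxa
    report$n_overlap_excluded <- sum(drop)
    report$n_taxa_overlap_excluded <- length(excluded_taxa)
    report$n_retained <- report$n_retained - sum(drop)
    report <- .report_fractions(report)
    kept <- kept[!drop, , drop = FALSE]
  }

  err_rows <- list()
  for (s in unique(kept$stage)) {
    tr <- estimate_stage(kept, s, estimator_cfg)
    e <- tr$estimates
    tt <- gen$truth[gen$truth$stage == s, , drop = FALSE]
    m <- merge(e[, c("stage", "bin_label", "hlm", "n")],
               tt, by = c("stage", "bin_label"))
    m$abs_error <- abs(m$hlm - m$t_true)
    err_rows[[s]] <- m
  }
  errors <- do.call(rbind, err_rows)
  if (!is.null(errors)) {
    errors <- errors[order(errors$stage, errors$bin_label),
                     c("stage", "bin_label", "t_true", "hlm", "abs_error", "n")]
    rownames(errors) <- NULL
  }
  list(errors = errors,
       max_abs_error = if (is.null(errors)) NA_real_ else max(errors$abs_error),
       report = report, excluded_taxa = excluded_taxa, records = kept,
       truth = gen$truth, planted = gen$planted)
}
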