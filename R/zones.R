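#' Climatic-zone temperature table
#'
#' The five marine climatic zones with their published shallow-water habitat
#' temperature ranges -- tropical 20-35, subtropical 18-25, warm temperate
#' (middle latitudes) 12-20, cool temperate (high latitudes) 4-10, polar
#' 0-4 degrees C -- and deep-water (below the 250-300 m cutoff, down to
#' ~500 m) ranges where stated: tropical up to 12 (operational lower bound
#' 5), warm temperate 5-7, cool temperate 1-4. The shallow table's
#' tropical/subtropical overlap (20-25) and the 10-12 degree gap between the
#' temperate zones are real features of the source ranges and are preserved,
#' not smoothed away; disambiguation lives in [nearest_zone()]. The nominal
#' latitude bands (used only by the plate-model consistency check) are a
#' declared convention: tropical |lat| < 25, subtropical 25-35, warm
#' temperate 35-50, cool temperate 50-65, polar >= 65.
#'
#' @param path Optional path to an editable CSV with the same columns,
#'   overriding the built-in table.
#' @return Data.frame `zone`, `depth`, `t_min_c`, `t_max_c`, `lat_min`,
#'   `lat_max`; zones ordered warm to cold.
#' @export
climatic_zone_table <- function(path = NULL) {
  if (!is.null(path)) {
    z <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(z)
  }
  zones <- c("tropical", "subtropical", "warm_temperate", "cool_temperate",
             "polar")
  shallow <- data.frame(
    zone = zones, depth = "shallow",
    t_min_c = c(20, 18, 12, 4, 0),
    t_max_c = c(35, 25, 20, 10, 4),
    lat_min = c(0, 25, 35, 50, 65),
    lat_max = c(25, 35, 50, 65, 90),
    stringsAsFactors = FALSE
  )
  deep <- data.frame(
    zone = c("tropical", "warm_temperate", "cool_temperate"),
    depth = "deep",
    t_min_c = c(5, 5, 1),
    t_max_c = c(12, 7, 4),
    lat_min = c(0, 35, 50),
    lat_max = c(25, 50, 65),
    stringsAsFactors = FALSE
  )
  rbind(shallow, deep)
}

.zone_rows <- function(depth, table) {
  z <- table[table$depth == depth, , drop = FALSE]
  if (nrow(z) == 0) stop("no zones for depth class: ", depth)
  z
}

#' Zones whose temperature range contains a value
#'
#' All bounds are inclusive. The result may be empty (the 10-12 degree gap
#' between the shallow temperate zones) or contain two zones (the 20-25
#' degree tropical/subtropical overlap).
#'
#' @param t Temperature, degrees C (scalar).
#' @param depth `"shallow"` (default) or `"deep"`.
#' @param table A [climatic_zone_table()].
#' @return Character vector of zone names (possibly empty).
#' @examples
#' zones_for_temperature(22)  # tropical, subtropical
#' zones_for_temperature(11)  # character(0)
#' @export
zones_for_temperature <- function(t, depth = c("shallow", "deep"),
                                  table = climatic_zone_table()) {
  stopifnot(is.finite(t))
  depth <- match.arg(depth)
  z <- .zone_rows(depth, table)
  z$zone[t >= z$t_min_c & t <= z$t_max_c]
}

#' Nearest zone to a temperature
#'
#' Resolves the published table's gaps and overlaps deterministically: the
#' zone minimizing the distance from `t` to its range (zero if inside), ties
#' broken toward the warmer zone.
#'
#' @inheritParams zones_for_temperature
#' @return A list: `zone` (name), `distance` (degrees C).
#' @examples
#' nearest_zone(11)  # warm_temperate, distance 1
#' @export
nearest_zone <- function(t, depth = c("shallow", "deep"),
                         table = climatic_zone_table()) {
  stopifnot(is.finite(t))
  depth <- match.arg(depth)
  z <- .zone_rows(depth, table)
  d <- pmax(0, z$t_min_c - t, t - z$t_max_c)
  i <- which.min(d)  # table ordered warm -> cold, so ties go warm
  list(zone = z$zone[i], distance = unname(d[i]))
}

#' Zone implied by a latitude
#'
#' Looks up |paleolat| in the nominal latitude bands of the zone table
#' (shallow rows). Bands are half-open `[lat_min, lat_max)` except the polar
#' band, which closes at 90.
#'
#' @param paleolat Latitude in degrees, |paleolat| <= 90.
#' @param table A [climatic_zone_table()].
#' @return Zone name.
#' @examples
#' zone_for_latitude(45)  # warm_temperate
#' @export
zone_for_latitude <- function(paleolat, table = climatic_zone_table()) {
  stopifnot(abs(paleolat) <= 90)
  a <- abs(paleolat)
  z <- .zone_rows("shallow", table)
  hit <- which(a >= z$lat_min & (a < z$lat_max | (a == 90 & z$lat_max == 90)))
  z$zone[hit[1]]
}

#' Check a bin estimate against a plate-model latitude
#'
#' The climatic-zone consistency check: does the temperature the fauna
#' implies (the bin's HLM) fall in the zone the plate model's paleolatitude
#' predicts? A mismatch flags either an exotic assemblage or a questionable
#' plate position -- the situation the consistency note describes.
#' When the HLM falls in one of the table's gaps the [nearest_zone()]
#' fallback arbitrates.
#'
#' @param estimate One-row data.frame with an `hlm` column (from
#'   [estimate_bin()]), or a bare numeric temperature.
#' @param model_latitude Latitude from the plate model, degrees.
#' @param table A [climatic_zone_table()].
#' @return A list of class `"zone_consistency"`: `hlm`, `matching_zones`,
#'   `model_zone`, `consistent`, `discrepancy_note`.
#' @examples
#' check_consistency(21, 60)  # tropical fauna vs cool-temperate latitude
#' @export
check_consistency <- function(estimate, model_latitude,
                              table = climatic_zone_table()) {
  hlm <- if (is.data.frame(estimate)) estimate$hlm[1] else as.numeric(estimate)
  stopifnot(is.finite(hlm))
  matching <- zones_for_temperature(hlm, "shallow", table)
  model_zone <- zone_for_latitude(model_latitude, table)
  if (length(matching)) {
    consistent <- model_zone %in% matching
    biota <- paste(matching, collapse = "/")
  } else {
    nz <- nearest_zone(hlm, "shallow", table)
    consistent <- identical(model_zone, nz$zone)
    biota <- paste0(nz$zone, " (nearest, ", format(nz$distance), " C off)")
  }
  note <- sprintf(
    "biota (HLM %.1f C) indicates %s; plate model latitude %.1f implies %s: %s",
    hlm, biota, model_latitude, model_zone,
    if (consistent) "consistent" else "inconsistent")
  structure(list(hlm = hlm, matching_zones = matching,
                 model_zone = model_zone, consistent = consistent,
                 discrepancy_note = note),
            class = "zone_consistency")
}

#' @export
print.zone_consistency <- function(x, ...) {
  cat(x$discrepancy_note, "\n")
  invisible(x)
}
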