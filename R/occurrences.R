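#' Flat occurrence format
#'
#' One row per taxon occurrence at one collection. The canonical columns are:
#' `record_id`, `collection_id`, `taxon_name`, `gbif_id`, `rank`, `stage`,
#' `subbasin`, `paleolat`, `paleolon`, `lat_modern`, `lon_modern`,
#' `depth_class`, `t_min_c`, `t_max_c`. Coordinates are signed decimal
#' degrees, north/east positive; temperatures are degrees C throughout.
#'
#' @return Character vector of the canonical column names.
#' @export
occurrence_fields <- function() {
  c("record_id", "collection_id", "taxon_name", "gbif_id", "rank", "stage",
    "subbasin", "paleolat", "paleolon", "lat_modern", "lon_modern",
    "depth_class", "t_min_c", "t_max_c")
}

.ranks <- c("species", "genus", "family", "order", "higher")
.depth_classes <- c("shallow", "deep", "unknown")

# keyword fallback for free-text bathymetry fields
.depth_keywords <- list(
  deep    = c("deep", "bathyal", "abyssal", "basinal"),
  shallow = c("shallow", "reef", "littoral", "neritic", "lagoon", "shelf")
)

.parse_depth_class <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% .depth_classes, x, NA_character_)
  miss <- which(is.na(out))
  for (i in miss) {
    if (is.na(x[i]) || !nzchar(x[i])) { out[i] <- "unknown"; next }
    if (any(vapply(.depth_keywords$deep, grepl, logical(1), x = x[i], fixed = TRUE)))
      out[i] <- "deep"
    else if (any(vapply(.depth_keywords$shallow, grepl, logical(1), x = x[i], fixed = TRUE)))
      out[i] <- "shallow"
    else out[i] <- "unknown"
  }
  out
}

#' Read occurrence records from a delimited file
#'
#' Reads a flat occurrence table, applying a column mapping from source-column
#' names to the canonical fields of [occurrence_fields()]. Rows failing
#' validation (inverted thermal range, unparseable temperature, out-of-bounds
#' coordinates, unknown stage) are skipped and logged with a row number and a
#' machine-readable reason code; valid rows are returned as a validated
#' data.frame.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names to
#'   source column names, e.g. `c(paleolat = "plat")`. Fields not mentioned
#'   are taken from identically named source columns. `gbif_id`, `rank`,
#'   `subbasin`, `paleolon`, `lat_modern`, `lon_modern` and `depth_class` are
#'   optional in the source (defaults `NA`, `"higher"`, `""`, `NA`, `NA`,
#'   `NA`, `"unknown"`).
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param check_stage Validate stage names against [stage_table()] after
#'   [normalize_stage()] (default `TRUE`).
#' @return A list with components `records` (validated data.frame in canonical
#'   columns), `skipped` (data.frame `row`, `reason`), and `n_skipped`.
#' @export
read_occurrences <- function(path, column_map = NULL, delim = ",",
                             check_stage = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty file: ", path)
  validate_occurrences(raw, column_map = column_map, check_stage = check_stage)
}

#' Validate a raw occurrence table
#'
#' The validation core behind [read_occurrences()], usable directly on an
#' in-memory data.frame.
#'
#' @param raw A data.frame of character columns (or coercible).
#' @inheritParams read_occurrences
#' @return Same structure as [read_occurrences()].
#' @export
validate_occurrences <- function(raw, column_map = NULL, check_stage = TRUE) {
  required <- c("record_id", "collection_id", "taxon_name", "stage",
                "paleolat", "t_min_c", "t_max_c")
  optional_default <- list(
    gbif_id = NA, rank = "higher", subbasin = "", paleolon = NA,
    lat_modern = NA, lon_modern = NA, depth_class = "unknown"
  )
  src <- stats::setNames(occurrence_fields(), occurrence_fields())
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), occurrence_fields())
    if (length(bad)) stop("column_map names unknown fields: ",
                          paste(bad, collapse = ", "))
    src[names(column_map)] <- column_map
  }
  for (f in required) {
    if (!src[[f]] %in% names(raw))
      stop("mapped column missing from input: ", src[[f]], " (field ", f, ")")
  }
  get_col <- function(f) {
    if (src[[f]] %in% names(raw)) as.character(raw[[src[[f]]]])
    else rep(as.character(optional_default[[f]]), nrow(raw))
  }
  n <- nrow(raw)
  rec <- data.frame(
    record_id     = get_col("record_id"),
    collection_id = get_col("collection_id"),
    taxon_name    = trimws(get_col("taxon_name")),
    gbif_id       = suppressWarnings(as.integer(get_col("gbif_id"))),
    rank          = tolower(trimws(get_col("rank"))),
    stage         = trimws(get_col("stage")),
    subbasin      = get_col("subbasin"),
    paleolat      = suppressWarnings(as.numeric(get_col("paleolat"))),
    paleolon      = suppressWarnings(as.numeric(get_col("paleolon"))),
    lat_modern    = suppressWarnings(as.numeric(get_col("lat_modern"))),
    lon_modern    = suppressWarnings(as.numeric(get_col("lon_modern"))),
    depth_class   = .parse_depth_class(get_col("depth_class")),
    t_min_c       = suppressWarnings(as.numeric(get_col("t_min_c"))),
    t_max_c       = suppressWarnings(as.numeric(get_col("t_max_c"))),
    stringsAsFactors = FALSE
  )
  rec$rank[!rec$rank %in% .ranks] <- "higher"

  reason <- rep(NA_character_, n)
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  flag(is.na(rec$t_min_c) | is.na(rec$t_max_c), "unparseable_temperature")
  flag(rec$t_min_c > rec$t_max_c, "inverted_thermal_range")
  flag(is.na(rec$paleolat) | abs(rec$paleolat) > 90, "bad_paleolat")
  flag(!is.na(rec$paleolon) & abs(rec$paleolon) > 180, "bad_paleolon")
  flag(!nzchar(rec$stage), "missing_stage")
  if (check_stage) {
    canon <- normalize_stage(rec$stage)
    flag(is.na(canon) & nzchar(rec$stage), "unknown_stage")
    ok_stage <- !is.na(canon)
    rec$stage[ok_stage] <- canon[ok_stage]
  }

  keep <- is.na(reason)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (any(keep) &&
      any(out$t_min_c < -5 | out$t_max_c > 45, na.rm = TRUE))
    warning("thermal ranges outside the plausible -5..45 degrees C envelope retained")
  skipped <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(records = out, skipped = skipped, n_skipped = nrow(skipped))
}

#' Write occurrence records to a delimited file
#'
#' Inverse of [read_occurrences()]: writes the canonical flat format so that
#' a read-back reproduces all fields of valid records.
#'
#' @param records Data.frame in canonical columns.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path, delim = ",") {
  utils::write.table(records[, occurrence_fields(), drop = FALSE], path,
                     sep = delim, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Join specification for a relational occurrence deposit
#'
#' Describes a three-table relational deposit: an occurrence table pointing at
#' a collection table (locality, stage, coordinates) and a taxon table
#' (identity and thermal tolerance). Defaults target the flat field names of
#' [occurrence_fields()] split across `occurrences.csv`, `collections.csv`,
#' `taxa.csv`; every element can be overridden to fit a live deposit whose
#' schema differs.
#'
#' @param occurrence_file,collection_file,taxon_file File names inside the
#'   deposit directory.
#' @param occurrence_key Column naming the occurrence identifier.
#' @param collection_key,taxon_key Foreign-key columns shared between the
#'   occurrence table and the collection/taxon tables.
#' @return A list with class `"paleosib_join_spec"`.
#' @export
paleosib_join_spec <- function(occurrence_file = "occurrences.csv",
                               collection_file = "collections.csv",
                               taxon_file = "taxa.csv",
                               occurrence_key = "record_id",
                               collection_key = "collection_id",
                               taxon_key = "taxon_id") {
  structure(list(occurrence_file = occurrence_file,
                 collection_file = collection_file,
                 taxon_file = taxon_file,
                 occurrence_key = occurrence_key,
                 collection_key = collection_key,
                 taxon_key = taxon_key),
            class = "paleosib_join_spec")
}

#' Load a relational occurrence deposit
#'
#' Reads the three tables of a PaleoSib-style relational deposit, joins them
#' into the flat occurrence format, and validates the result. Occurrences
#' whose collection or taxon key resolves to no row are skipped and counted
#' as dangling; duplicated occurrence identifiers are a hard error. Taxon
#' level thermal ranges are broadcast to every record of the taxon.
#'
#' @param directory Directory containing the deposit tables.
#' @param join_spec A [paleosib_join_spec()].
#' @param check_stage Passed to [validate_occurrences()].
#' @return A list: `records` (validated data.frame), `totals` (list with
#'   `n_records`, `n_collections`, `n_taxa` of the loaded census),
#'   `n_dangling`, `skipped` (validation skip log).
#' @export
load_paleosib_deposit <- function(directory, join_spec = paleosib_join_spec(),
                                  check_stage = TRUE) {
  js <- join_spec
  rd <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) stop("deposit table not found: ", p)
    utils::read.csv(p, colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE)
  }
  occ <- rd(js$occurrence_file)
  col <- rd(js$collection_file)
  tax <- rd(js$taxon_file)
  for (nm in c(js$occurrence_key, js$collection_key, js$taxon_key))
    if (!nm %in% names(occ)) stop("occurrence table lacks key column: ", nm)
  if (anyDuplicated(occ[[js$occurrence_key]]))
    stop("duplicate occurrence identifiers in ", js$occurrence_file)

  i_col <- match(occ[[js$collection_key]], col[[js$collection_key]])
  i_tax <- match(occ[[js$taxon_key]], tax[[js$taxon_key]])
  dangling <- is.na(i_col) | is.na(i_tax)
  n_dangling <- sum(dangling)
  occ <- occ[!dangling, , drop = FALSE]
  i_col <- i_col[!dangling]; i_tax <- i_tax[!dangling]

  pick <- function(df, idx, field, default = NA) {
    if (field %in% names(df)) as.character(df[[field]])[idx]
    else rep(as.character(default), length(idx))
  }
  flat <- data.frame(
    record_id     = occ[[js$occurrence_key]],
    collection_id = occ[[js$collection_key]],
    taxon_name    = pick(tax, i_tax, "taxon_name"),
    gbif_id       = pick(tax, i_tax, "gbif_id"),
    rank          = pick(tax, i_tax, "rank", "higher"),
    stage         = pick(col, i_col, "stage"),
    subbasin      = pick(col, i_col, "subbasin", ""),
    paleolat      = pick(col, i_col, "paleolat"),
    paleolon      = pick(col, i_col, "paleolon"),
    lat_modern    = pick(col, i_col, "lat_modern"),
    lon_modern    = pick(col, i_col, "lon_modern"),
    depth_class   = pick(col, i_col, "depth_class", "unknown"),
    t_min_c       = pick(tax, i_tax, "t_min_c"),
    t_max_c       = pick(tax, i_tax, "t_max_c"),
    stringsAsFactors = FALSE
  )
  # per-record temperature assignments, when present, override the taxon level
  for (f in c("t_min_c", "t_max_c"))
    if (f %in% names(occ)) {
      v <- occ[[f]]
      use <- !is.na(v) & nzchar(v)
      flat[[f]][use] <- v[use]
    }
  val <- validate_occurrences(flat, check_stage = check_stage)
  totals <- list(
    n_records = nrow(val$records),
    n_collections = length(unique(val$records$collection_id)),
    n_taxa = length(unique(val$records$taxon_name))
  )
  list(records = val$records, totals = totals, n_dangling = n_dangling,
       skipped = val$skipped)
}

#' Write and read per-bin temperature estimates
#'
#' Serializes bin estimates as delimited text with the header
#' `Stage, Paleolatitude, n, n_int, HLM, Q1, Q3, IQR`, temperatures formatted
#' with three decimals so a read-back reproduces the written values exactly at
#' that precision.
#'
#' @param estimates Data.frame of bin estimates (from [estimate_stage()] or
#'   [paleotherm()]), with columns `stage`, `bin_label`, `n`, `n_int`, `hlm`,
#'   `q1`, `q3`, `iqr`.
#' @param path Output file path.
#' @return `write_bin_estimates()` returns `path` invisibly;
#'   `read_bin_estimates()` returns the estimates data.frame.
#' @export
write_bin_estimates <- function(estimates, path) {
  if (is.null(estimates) || nrow(estimates) == 0)
    stop("no estimates to write")
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  out <- data.frame(
    Stage = estimates$stage,
    Paleolatitude = estimates$bin_label,
    n = estimates$n,
    n_int = estimates$n_int,
    HLM = fmt(estimates$hlm),
    Q1 = fmt(estimates$q1),
    Q3 = fmt(estimates$q3),
    IQR = fmt(estimates$iqr),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_estimates
#' @export
read_bin_estimates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(stage = x$Stage, bin_label = x$Paleolatitude, n = x$n,
             n_int = x$n_int, hlm = x$HLM, q1 = x$Q1, q3 = x$Q3, iqr = x$IQR,
             stringsAsFactors = FALSE)
}
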