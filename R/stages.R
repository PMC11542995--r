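#' Devonian-Triassic stage chart
#'
#' The chronostratigraphic frame the estimator works in: 29 stage-level time
#' slices spanning the Lochkovian (Early Devonian) through the Norian (Late
#' Triassic), with ages in millions of years before present (older bound
#' `age_max_ma`, younger bound `age_min_ma`). Stage names follow the
#' International Chronostratigraphic Chart; the chart is ordered oldest first
#' and adjacent stages share boundary ages.
#'
#' @return A data.frame with columns `stage`, `system`, `age_min_ma`,
#'   `age_max_ma`, one row per stage, 29 rows.
#' @examples
#' st <- stage_table()
#' nrow(st)                 # 29
#' st[st$stage == "Pragian", ]
#' @export
stage_table <- function() {
  st <- data.frame(
    stage = c(
      "Lochkovian", "Pragian", "Emsian", "Eifelian", "Givetian",
      "Frasnian", "Famennian",
      "Tournaisian", "Visean", "Serpukhovian", "Bashkirian", "Moscovian",
      "Kasimovian", "Gzhelian",
      "Asselian", "Sakmarian", "Artinskian", "Kungurian", "Roadian",
      "Wordian", "Capitanian", "Wuchiapingian", "Changhsingian",
      "Induan", "Olenekian", "Anisian", "Ladinian", "Carnian", "Norian"
    ),
    system = c(
      rep("Devonian", 7), rep("Carboniferous", 7), rep("Permian", 9),
      rep("Triassic", 6)
    ),
    age_max_ma = c(
      419.2, 410.8, 407.6, 393.3, 387.7, 382.7, 372.2,
      358.9, 346.7, 330.9, 323.2, 315.2, 307.0, 303.7,
      298.9, 293.5, 290.1, 283.5, 273.0, 266.9, 264.3, 259.5, 254.1,
      251.9, 251.2, 247.2, 242.0, 237.0, 227.0
    ),
    age_min_ma = c(
      410.8, 407.6, 393.3, 387.7, 382.7, 372.2, 358.9,
      346.7, 330.9, 323.2, 315.2, 307.0, 303.7, 298.9,
      293.5, 290.1, 283.5, 273.0, 266.9, 264.3, 259.5, 254.1, 251.9,
      251.2, 247.2, 242.0, 237.0, 227.0, 208.5
    ),
    stringsAsFactors = FALSE
  )
  st[, c("stage", "system", "age_min_ma", "age_max_ma")]
}

#' Normalize stage names
#'
#' Matches stage names case-insensitively after trimming whitespace, and
#' resolves common spelling variants through an editable alias table (bundled
#' at `inst/extdata/stage_aliases.csv`). Unrecognized names are returned as
#' `NA`.
#'
#' @param x Character vector of stage names as they appear in a source table.
#' @param aliases Optional data.frame with columns `alias`, `stage` overriding
#'   the bundled alias table.
#' @return Character vector of canonical stage names (`NA` where unmatched).
#' @examples
#' normalize_stage(c(" pragian ", "Changxingian", "nonsense"))
#' @export
normalize_stage <- function(x, aliases = NULL) {
  if (is.null(aliases)) {
    path <- system.file("extdata", "stage_aliases.csv", package = "paleotherm")
    aliases <- if (nzchar(path)) utils::read.csv(path, stringsAsFactors = FALSE)
               else data.frame(alias = character(), stage = character())
  }
  canon <- stage_table()$stage
  key <- tolower(trimws(as.character(x)))
  out <- canon[match(key, tolower(canon))]
  miss <- is.na(out)
  if (any(miss) && nrow(aliases)) {
    hit <- match(key[miss], tolower(trimws(aliases$alias)))
    out[miss] <- aliases$stage[hit]
  }
  out
}
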