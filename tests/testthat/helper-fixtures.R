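# Programmatic fixtures shared across the test files.

# a small, fully valid flat occurrence data.frame
make_records <- function(stage = "Pragian", paleolat = c(12, 13, 22, 23, 31),
                         t_min = c(20, 21, 18, 17, 15),
                         t_max = c(23, 24, 21, 20, 18),
                         depth = "shallow", taxon = NULL) {
  n <- length(paleolat)
  if (is.null(taxon)) taxon <- sprintf("Taxon_%02d", seq_len(n))
  data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    collection_id = sprintf("c%03d", seq_len(n)),
    taxon_name = taxon,
    gbif_id = seq_len(n),
    rank = "genus",
    stage = stage,
    subbasin = "Nordvik",
    paleolat = paleolat,
    paleolon = 90,
    lat_modern = paleolat + 20,
    lon_modern = 100,
    depth_class = rep_len(depth, n),
    t_min_c = rep_len(t_min, n),
    t_max_c = rep_len(t_max, n),
    stringsAsFactors = FALSE
  )
}

# write a toy three-table relational deposit; returns its directory
make_mini_deposit <- function(dir = tempfile("deposit"),
                              drop_collection = FALSE) {
  dir.create(dir)
  occ <- data.frame(
    record_id = c("o1", "o2", "o3", "o4"),
    collection_id = c("c1", "c1", "c2", "c2"),
    taxon_id = c("t1", "t2", "t2", "t3")
  )
  col <- data.frame(
    collection_id = c("c1", "c2"),
    stage = c("Pragian", "Pragian"),
    subbasin = c("Nordvik", "Vilyui"),
    paleolat = c(21.5, 33.0), paleolon = c(80, 95),
    lat_modern = c(62, 68), lon_modern = c(100, 110),
    depth_class = c("shallow", "shallow")
  )
  tax <- data.frame(
    taxon_id = c("t1", "t2", "t3"),
    taxon_name = c("Favosites", "Spirifer", "Cyrtospirifer"),
    gbif_id = c(101, 102, 103), rank = "genus",
    t_min_c = c(20, 18, 15), t_max_c = c(24, 21, 19)
  )
  if (drop_collection) col <- col[col$collection_id != "c2", ]
  write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  write.csv(col, file.path(dir, "collections.csv"), row.names = FALSE)
  write.csv(tax, file.path(dir, "taxa.csv"), row.names = FALSE)
  dir
}

# independent Hodges-Lehmann oracle: explicit double loop, no outer()
hl_oracle <- function(x) {
  n <- length(x)
  walsh <- numeric(n * (n + 1) / 2)
  k <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    k <- k + 1L
    walsh[k] <- (x[i] + x[j]) / 2
  }
  sw <- sort(walsh)
  m <- length(sw)
  if (m %% 2 == 1) sw[(m + 1) / 2] else (sw[m / 2] + sw[m / 2 + 1]) / 2
}

# enumerate all multisets of given size from a value grid
multisets_from_grid <- function(grid, size) {
  combn(length(grid) + size - 1, size, function(ix) grid[ix - seq_len(size) + 1],
        simplify = FALSE)
}
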