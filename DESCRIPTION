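Package: paleotherm
Title: Biotic Sea-Surface Paleotemperature Estimation from Fossil Occurrences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sea-surface paleotemperatures from the taxonomic
    composition of fossil assemblages. Occurrence records carrying
    thermal-tolerance ranges are ecologically screened (tolerance width,
    bathymetry, exotic migrants), grouped into paleolatitudinal bins, and
    summarised per stage and bin with a robust pipeline: deduplication of
    identical temperature intervals, Tukey-fence outlier removal, and the
    Hodges-Lehmann pseudo-median. Includes climatic-zone temperature tables
    with plate-model consistency checks, loaders for flat and relational
    occurrence deposits, and a seeded synthetic-data generator so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
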