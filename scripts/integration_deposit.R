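#!/usr/bin/env Rscript
# Optional integration run against a locally downloaded PaleoSib deposit
# (Zenodo, DOI 10.5281/zenodo.13227985; not bundled -- download separately).
#
#   Rscript scripts/integration_deposit.R --deposit-dir <dir> [--stage Pragian]
#
# Checks the loader census (23,580 records from 5229 collections), the
# Pragian screening split (448 admitted = 347 narrow + 101 moderate), and the
# published Pragian per-bin statistics (HLM 22.625 / 19.625 / 19 / 19 at
# paleolatitudes 10/20/30/40) under the documented dedupe/quartile
# conventions.  The live deposit's column names may need a custom
# paleosib_join_spec(); adjust below if the schema differs.

suppressPackageStartupMessages(library(paleotherm))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
dir <- arg("--deposit-dir")
stage <- arg("--stage", "Pragian")
if (is.null(dir)) stop("--deposit-dir is required (path to the deposit CSVs)")

dep <- load_paleosib_deposit(dir)
cat(sprintf("census: %d records, %d collections, %d taxa (%d dangling keys)\n",
            dep$totals$n_records, dep$totals$n_collections,
            dep$totals$n_taxa, dep$n_dangling))
cat(sprintf("expected census: 23580 records, 5229 collections -> %s\n",
            if (dep$totals$n_records == 23580 &&
                dep$totals$n_collections == 5229) "MATCH" else "MISMATCH"))

sub <- dep$records[dep$records$stage == stage, , drop = FALSE]
adm <- filter_admissible(sub, screening_config())
r <- adm$report
cat(sprintf("%s screening: %d admitted (%d narrow, %d moderate); expected 448 = 347 + 101 -> %s\n",
            stage, r$n_retained, r$n_narrow, r$n_moderate,
            if (r$n_retained == 448 && r$n_narrow == 347 &&
                r$n_moderate == 101) "MATCH" else "MISMATCH"))

# published per-bin statistics are tried under every documented convention
expected <- data.frame(bin_label = c(10, 20, 30, 40),
                       hlm = c(22.625, 19.625, 19, 19))
for (dd in c("unique", "weighted")) for (qm in c("interp_orderstat",
                                                 "inclusive", "exclusive")) {
  cfg <- estimator_config(dedupe_mode = dd, quartile_method = qm)
  tr <- estimate_stage(adm$records, stage, cfg)
  m <- merge(tr$estimates, expected, by = "bin_label",
             suffixes = c("", "_pub"))
  ok <- nrow(m) == 4 && all(abs(m$hlm - m$hlm_pub) < 0.005)
  cat(sprintf("  dedupe=%-8s quartiles=%-16s -> %s\n", dd, qm,
              if (ok) "HLM MATCH" else "no match"))
  if (ok) print(tr$estimates[, c("bin_label", "n", "n_int", "hlm",
                                 "q1", "q3", "iqr")], row.names = FALSE)
}
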