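---
title: "Estimating sea-surface paleotemperatures from fossil assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sea-surface paleotemperatures from fossil assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleotherm)
```

## The proxy and its model

Marine invertebrate taxa are confined to characteristic habitat-temperature
intervals: a reef coral and an agglutinated foraminifer do not tolerate the
same water. When a fossil assemblage is read through a catalogue of such
thermal tolerances, every occurrence record becomes a (noisy, interval-valued)
observation of the sea-surface temperature (SST) at its paleolatitude and
chronostratigraphic stage. `paleotherm` turns a table of such records into
per-(stage, latitude-bin) temperature estimates.

The model is deliberately minimal. Each record `i` carries a thermal
tolerance `[t_min, t_max]` for its taxon; its point evidence is the interval
midpoint `m_i = (t_min + t_max) / 2`. Within one stage and one 10-degree
paleolatitudinal bin, midpoints from many taxa form a sample around the bin's
true SST, but the sample is unbalanced (abundant taxa recur across many
collections), contaminated (misattributed bathymetry, exotic migrants) and
distinctly non-normal. The pipeline addresses each distortion in turn:

1. **Ecological screening.** Records whose tolerance width `t_max - t_min`
   exceeds 5 °C carry too little information and are dropped; widths up to
   3 °C are tallied as *narrow*, 3–5 °C as *moderate* (both inclusive at the
   boundary). Deep-water records — habitat below the 250–300 m cutoff,
   default 300 m — reflect permanently cold bottom water, not SST, and are
   excluded; records of unknown bathymetry are retained with a warning,
   because only a habitat known to be exclusively deep disqualifies a taxon.
2. **Exotic-migrant exclusion.** Taxa whose range belongs simultaneously to
   a warm ("red") and a cold ("blue") grade set are wide-ranging or
   out-of-zone migrants; all records of such a taxon are removed
   (taxon-level, because the conflict is a property of the taxon's habit).
3. **Deduplication.** Identical tolerance intervals (equality after rounding
   to 0.01 °C) are collapsed to unique intervals with multiplicities,
   so `n` (records) and `n_int` (unique intervals) are both reported and an
   over-collected taxon cannot dominate its bin.
4. **Tukey fences.** One non-iterated pass removes values outside
   `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` (inclusive fences; constant data are never
   touched).
5. **Hodges–Lehmann pseudo-median.** The estimate `HLM` is the median of all
   Walsh averages `(x_i + x_j)/2`, `i ≤ j`, self-pairs included — robust to
   the skewed mixtures that assemblages of warm- and cold-leaning taxa
   produce, and exactly the sample median's breakdown-friendly cousin for
   the small `n_int` (often 3–15) a bin yields.

Each bin row reports `n`, `n_int`, `HLM`, `Q1`, `Q3` and `IQR = Q3 − Q1`.
The quartiles are reported **pre-Tukey**, so the published `IQR` is the one
that defined the fences (a post-hoc quartile of the trimmed sample would
disagree with its own filtering rule); `n` and `n_int` likewise count the
bin before outlier removal.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `max_tolerance_width` | 5 | °C | admissibility bound on tolerance width (inclusive) |
| `narrow_cutoff` | 3 | °C | narrow/moderate boundary (inclusive) |
| `deep_cutoff_m` | 300 | m | habitat depth separating surface from deep evidence |
| `bin_width` | 10 | ° | paleolatitudinal bin width |
| `tukey_k` | 1.5 | – | fence multiplier |
| `quartile_method` | `interp_orderstat` | – | quartile convention (below) |
| `dedupe_mode` | `unique` | – | estimator input: unique intervals vs multiplicity-weighted |
| `min_bin_n` | 5 | records | low-confidence flag threshold |

The admissibility bound is *inclusive* at 5 °C: the narrow (≤ 3) and
moderate (3–5) classes must together close the admissible set, which an
exclusive bound would contradict. The 300 m default is the permissive end of
the 250–300 m convention; the band's ambiguity is deliberately left in the
configuration rather than resolved silently.

### Bin convention

Bin labels are the nearest multiples of `bin_width`; each bin spans
`[label − width/2, label + width/2)` with exact boundaries going to the
higher label, and hemispheres are never merged (the label keeps the
latitude's sign). Center-labelled bins make the label itself the natural
evaluation point of a latitudinal gradient; an edge-labelled convention
would shift every comparison by half a bin.

### Quartile conventions

No single quartile definition is canonical for small samples, and with
`n_int` as small as 3 the choice is visible in the output. The default
`interp_orderstat` interpolates the sorted values at position `p·(m−1)`
(R's type 7). `inclusive` (Tukey hinges) and `exclusive` (R's type 6) are
provided so results can be calibrated against tables computed elsewhere;
the deposit-integration script tries all three.

### Estimator input: unique intervals

`dedupe_mode = "unique"` (the default) feeds the estimator one value per
unique interval. Reported record counts far exceed unique-interval counts
in real occurrence compilations, and sampling intensity is a property of
collection effort, not of climate; weighting by multiplicity would let one
heavily collected taxon move the bin estimate. `"weighted"` mode is provided
for sensitivity analysis.

## Climatic zones and the consistency check

The five-zone table encodes published shallow-water habitat ranges —
tropical 20–35, subtropical 18–25, warm temperate 12–20, cool temperate
4–10, polar 0–4 °C — and deep-water ranges where stated (tropical up to
12 °C with an operational lower bound of 5 °C, warm temperate 5–7,
cool temperate 1–4). The table's tropical/subtropical overlap (20–25 °C)
and its 10–12 °C gap are *features of the published ranges* and are kept
verbatim: `zones_for_temperature()` may therefore return two zones or none.
Disambiguation is confined to `nearest_zone()` (minimal distance to a range,
ties toward the warmer zone), so the encoded table remains quotable.

`check_consistency()` compares the zone(s) a bin's HLM implies with the zone
a plate-model paleolatitude predicts. The nominal latitude bands — tropical
< 25°, subtropical 25–35°, warm temperate 35–50°, cool temperate 50–65°,
polar ≥ 65° — are a declared convention (zone maps are drawn, not
tabulated), used only by this check and overridable through the zone-table
CSV. A mismatch — say, a tropical-temperature fauna in a sub-basin a plate
model places at 60° — flags either an exotic assemblage or a questionable
plate reconstruction; the check reports, it does not adjudicate.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the estimator
assumes so the full pipeline is testable without any external download:

- a linear SST gradient `T(l) = 25 − 0.25·|l|` °C (its slope and intercept
  configurable) over home latitudes 5–45°, spanning four 10° bins;
- 100 taxa, each with a home latitude, a true temperature equal to the
  gradient value plus taxon-level noise (sd 1 °C), and a tolerance interval
  of uniform width 1–5 °C centred on that temperature (bounds rounded to
  0.1 °C);
- about 7 records per taxon scattered within ±2° of the home latitude, so
  record counts exceed unique-interval counts as they do in compilations;
- exactly `round(0.09 · n_taxa)` taxa planted as deep-water-only and
  `round(0.03 · n_taxa)` as exotic warm-water migrants at high latitude,
  their intervals shifted +10 °C — the contamination rates the screening
  rules exist for.

Two modelling choices deserve a note. The taxon-level noise is a normal
truncated at ±2 sd: thermal niches scatter around the local SST but do not
stray arbitrarily far from it, and bounded scatter makes the planted
contamination *exactly* separable — the screening tests can then demand
exact recovery of the planted 9 %/3 % fractions rather than approximate
ones. And `recovery_experiment()` detects migrants per latitudinal bin,
with a grade spec whose warm set starts half an `exotic_offset` above the
local gradient value (midpoint rule, cold set spanning the whole habitable
range), so a migrant belongs to both sets and classifies `"both"`. A single
global warm/cold split cannot work here: once the latitudinal span of the
data exceeds the offset, a migrant at high latitude is colder than an
honest tropical local.

What the generator does **not** emulate: taphonomic and sampling-effort
bias, stage-boundary correlation error, spatially clustered collections,
asymmetric or multimodal tolerance intervals, and real catalogues' errors
in the tolerance assignments themselves. A passing recovery test therefore
shows the pipeline recovers a known gradient under idealized sampling — it
does not validate any particular tolerance catalogue.

## Numerical choices and degenerate inputs

- Midpoints are carried at full floating precision; only interval *identity*
  (for deduplication) uses 0.01 °C rounding, to absorb text-parsing noise.
- Empty bins emit no estimate row; an empty stage yields an empty trend with
  a warning; an empty input dataset yields a zeroed screening report, not an
  error.
- `hodges_lehmann()` and `quartiles()` on an empty set are hard errors — a
  silent `NA` would propagate into written tables.
- Tukey fences are inclusive, so zero-IQR (constant) bins retain all values.
- Ties in `nearest_zone()` break toward the warmer zone; ties in bin
  assignment (exact boundary) go to the higher label. Both are arbitrary but
  fixed and documented.
- The stage chart spans Lochkovian–Norian: 29 stage-level slices. (The
  Rhaetian is omitted; marine stage-level records for it are too sparse in
  the target region to carry a bin estimate.) Stage names are matched
  case-insensitively with a bundled, editable alias table for common
  spelling variants.

## Problem sizes in the test suite

The suite checks the Hodges–Lehmann implementation against an independent
brute-force enumeration over *all* 1 286 multisets of size ≤ 8 from a
5-value grid plus 1 000 random sets; Tukey conservation/idempotence over
1 000 random inputs; and parameter recovery on the default generator (100
taxa, ~700 records, four bins, seed 42), demanding every bin HLM within
±1 °C of the true bin-centre value, a non-increasing trend, and exact
recovery of the planted contamination fractions. These sizes keep the full
suite under a minute while the exhaustive small-sample check leaves no
gap for the estimator's core.

## Known limitations

- Paleocoordinates are inputs, taken from whatever rotation model produced
  them; the package neither rotates plates nor propagates rotation
  uncertainty.
- No confidence intervals accompany the HLM (none are defined in the
  pipeline being implemented); a bootstrap over unique intervals would be a
  natural extension.
- The trend is piecewise-linear through (bin, HLM) points by design — no
  smoothing is applied, so single-bin wiggles are visible and real.
- Zone latitude bands are a fixed convention; through deep time the real
  bands migrate with global climate state, which is precisely what the
  consistency check is meant to surface, not correct for.

## A worked run

```{r example, eval = FALSE}
gen <- generate_dataset(synthetic_spec(seed = 42))
fit <- paleotherm(gen$records)
summary(fit)
coef(fit)
predict(fit, data.frame(stage = "Pragian", paleolat = 23))
plot(fit)
check_consistency(coef(fit)[1], model_latitude = 60)
```
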