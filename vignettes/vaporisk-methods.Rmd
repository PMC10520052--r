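---
title: "Methods: multi-route risk assessment of e-cigarette chemicals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-route risk assessment of e-cigarette chemicals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaporisk)
```

## The assessment model

vaporisk assesses the health risks of eleven chemicals found in e-cigarette
aerosols and liquids — four organic compounds generated mainly by heating
the propylene-glycol/glycerine solvents (formaldehyde, acetaldehyde,
acetone, acrolein) and seven heavy metals that migrate from coils, wicks and
solder (As, Cd, Mn, Pb, Cu, Ni, Cr) — across three exposure routes.
Aerosol concentrations (µg/puff) drive inhalation; e-liquid concentrations
(mg/ml) drive oral and dermal contact through device leakage, and a one-off
10 ml accidental ingestion drives the acute assessment.

Chronic daily doses are the standard intake-rate products:

* inhalation: `DD = P · T · EF · ED / (BW · AT)` with `T` puffs/day;
* oral: `DD = P · CI · CF · EF · ED / (BW · AT)` with `CI` the daily
  leakage contact volume;
* dermal: `DD = P · CI · CF · SA · AF · ABS · EF · ED / (BW · AT)`;
* acute: `I = P · AI / BW` (mg/kg, oral and dermal only — users do not
  inhale very large aerosol quantities in a short time, so no acute
  inhalation pathway is modelled).

Risks follow as `CR = CPV · DD` (cancer, acceptable below 10⁻⁶),
`HQ = DD / R` (non-cancer, acceptable below 1, high above 10) and
`AR = I / LD50` (acute, unacceptable above 1). Route totals (`HI`, total
`CR`, total `AR`) are straight sums of independent per-chemical risks; no
synergistic or antagonistic interactions are modelled. Chromium is treated
as hexavalent throughout, since the source literature rarely speciates it
and Cr(VI) is the hazardous form.

### Scenario parameters

| parameter | default | units | rationale |
|---|---|---|---|
| BW | 70 | kg | EPA default adult |
| T | 163 | puffs/day | mean daily puff count of e-cigarette users |
| M (breathing volume) | 20 | m³/day | EPA default; used only to convert airborne thresholds to doses |
| CI | 0.05 | ml/day | ~1% of a 5 ml/day consumption reaching skin/mouth via leakage |
| AI | 10 | ml | one accidentally ingested e-liquid bottle charge |
| EF, ED, AT | 365 d/y, 70 y, 25550 d | | lifetime exposure; EF·ED/AT = 1 exactly |
| SA | 5700 | cm² | exposed skin area |
| AF | 0.2 | mg/(cm²·day) | skin adherence factor |
| ABS | 0.03 (`paper_replication`) | — | see below |
| CF | 1 | — | canonical units are already consistent |

### The dermal equation and the dual ABS mode

As printed, the dermal chronic equation is dimensionally inconsistent: a
volume (ml) multiplied by an area (cm²) and an adherence factor
(mg/(cm²·day)) cannot yield mg/day for a concentration in mg/ml. The
implementation applies the product `CI·SA·AF·ABS` literally as a single
multiplier with `CF = 1`, which is what reproduces the reference dose table
cell-for-cell. Back-solving every reference dermal dose further shows that a
single absorption fraction `ABS = 0.03` was applied to *all* chemicals,
although the stated methodology assigns 0.03 to As and 0.001 to everything
else. Both readings are available: `dermal_mode = "paper_replication"`
(default, `ABS = 0.03` everywhere) and `"as_stated"` (0.03 for As, 0.001
otherwise); the two differ by the factor 0.001/0.03 for non-As chemicals.

### The minimum-reference rule

For inhalation, two non-cancer thresholds can coexist (an OEHHA REL and a
USEPA RfC, both µg/m³). Each is converted to a dose by
`c × breathing_volume / BW / 1000` and the smaller converted value is used —
the conservative choice. Oral and dermal use the applicable RfD directly,
with no additional dermal absorption adjustment of the RfD (this matches
the reference hazard-quotient table, e.g. the Cd dermal cell). A missing
threshold means the assessment is *not performed* for that cell: it is
reported as `NA`, excluded from route totals, and never coerced to zero.

## Packaged data and its resolution

The packaged fixtures transcribe the compiled literature summaries
(mean, SD, min, max, number of source articles per chemical and matrix) and
the toxicity reference tables. Three issues in the source tables required
explicit resolution, all documented in
`inst/extdata/tables/toxicity_resolution.csv` and the `as_printed` columns of
the summary fixtures:

* several reference-table rows print concatenated digit strings; they were
  resolved by back-solving against the published dose and risk tables
  (Cr: REL 0.2, CPV 510, RfC 0.0083; Cd: REL 0.02, CPV 15; acetaldehyde:
  REL 140, RfC 9, with the inhalation CPV set to the OEHHA value 0.01 —
  the only value that reproduces the published acetaldehyde cancer risk);
* the aerosol acetone/acrolein summary rows are transposed relative to
  every downstream table; the default `"as_used"` variant of
  `packaged_summaries()` adopts the internally consistent assignment
  (acrolein 0.373 µg/puff, acetone 0.242 µg/puff) and the printed variant
  stays loadable with a warning;
* the published acute-risk cells for acetone and acrolein are each
  consistent only with the *other* substance's LD50; `acute_risk()`
  computes the ratio faithfully with each chemical's own LD50, so those two
  cells intentionally differ from the source. The same pairing affects the
  published oral hazard quotients of the two substances.

Two published values resist reconstruction: the Pb inhalation HQ implies a
reference near 0.465 µg/m³ rather than the tabulated REL 0.5 (the fixture
keeps 0.5), and the Cr inhalation HQ is ~4% above its own dose divided by
the minimum reference. Both discrepancies are absorbed by the hazard-index
tolerance and neither is treated as an individually reproducible quantity.

Non-detects are encoded as concentration 0 (the compiled ranges start at 0
and absorption is assumed complete); no LOD/2 substitution is applied.
A single-sample summary has SD 0 by convention so that summaries are total
functions. Whether the transcribed SDs are sample or population statistics
is not stated in the source; `summarize_concentrations()` documents its own
n−1 convention.

## The probabilistic layer

Sample-level concentration data are fitted by maximum likelihood to the
candidate set {normal, lognormal, gamma, Weibull, uniform, triangular} —
the common set of spreadsheet risk tools — with selection by the smallest
Anderson–Darling statistic; a chi-square statistic on equiprobable bins is
recorded as a secondary diagnostic but does not drive selection, since the
source workflow names both tests without a combination rule. Numerical
choices:

* zeros are modelled as a point mass whose weight is the observed zero
  fraction, mixed with a positive-part fit for the strictly positive
  families; the real-line families are fitted to all values and their
  negative Monte Carlo draws are truncated at 0;
* uniform and triangular endpoints are widened by `range/n` beyond the
  sample extremes so no observation sits at `F = 0` or `F = 1` (where the
  AD statistic diverges); the triangular mode is found by a 1-D likelihood
  search;
* gamma and Weibull fits are performed on mean-scaled data and transformed
  back, for numerical stability at the µg-scale concentrations involved;
* fewer than 8 samples (or fewer than 2 distinct positive values) fall
  back to the empirical distribution; an all-identical sample degenerates
  to a point mass with a warning; fewer than 2 samples is an error.

Monte Carlo propagation draws `nsim = 10000` concentration vectors
(one seeded generator per run, seed recorded in the result), evaluates the
full deterministic pipeline per draw, and reports percentiles
{1, 5, 25, 50, 75, 95, 99}, means, and exceedance probabilities against the
kind-specific thresholds. Only concentrations are stochastic by default;
scenario constants stay fixed, which matches the observation that the
sensitivity of the outputs is dominated by concentrations. Sensitivity is
the normalized squared Spearman rank correlation
(`r_i²/Σr_j² × 100`), the conventional "contribution to variance" measure;
"contribution calculated by the square of the variance" in the source is
read as exactly this quantity.

When only summaries exist (the packaged case), `simulate()` defaults to
lognormal distributions moment-matched to each summary's mean and SD, and
`surrogate_samples()` can materialize quantile-spaced surrogate values for
fitting. Both constructions are package conveniences that inherit only the
summary's first two moments — they are not part of the source methodology
and are labelled as such.

## The synthetic-data generator

`generate_studies()` emulates the *structure* of a literature compilation:
independent studies that report individual values, a mean only, a range
only (min/max of a batch of 5), or a 3-point power-level series that gets
averaged. Ground truth defaults to a lognormal (concentrations are
non-negative and strongly right-skewed; the compiled SD exceeds the mean
for most aerosol chemicals). `generate_paper_like_study()` moment-matches
the ground truth to the packaged means/SDs, uses the printed study counts,
a 50/20/20/10 reporting mix, 3 measurements per individual study, and a 2%
non-detect rate for chemicals whose compiled range touches zero —
non-detects occur in this literature but are uncommon, with means sitting
far above zero.

The generator does *not* model device physics (power and coil effects on
carbonyl yield), between-chemical correlation (a shared device produces
correlated metal concentrations), or measurement error; passing tests
therefore demonstrate the correctness of the pipeline's statistics on
literature-shaped data, not the fidelity of any particular synthetic
dataset to real products.

## Known limitations

* Tail exceedance probabilities estimated from literature-scale samples
  (10–20 values per chemical) are intrinsically unstable: the fitted
  log-scale SD carries enough error to move an exceedance estimate by tens
  of percentage points. The package's validation therefore checks exact
  exceedance against closed forms at large n, and checks only the
  *ordering* of dominant vs negligible contributors at literature scale.
  The same caveat applies to any spreadsheet reproduction of this workflow.
* Route totals assume additive, independent risks; organ-specific
  aggregation and chemical interactions are out of scope.
* Only the 70-kg adult scenario is modelled; adolescents, with developing
  organ systems and lower body weight, would need their own scenario
  object (the constructor accepts arbitrary constants).
* The oral/dermal chronic contact volume (0.05 ml/day) is applied to each
  route in full, not split between them — the reading that reproduces the
  reference dose table; and the worst-case totals combine all per-chemical
  maxima simultaneously, a deliberately pessimistic co-occurrence.

## Problem sizes used in validation

The deterministic benchmark panel runs on the 11-chemical packaged tables
in milliseconds. Property-based validation uses 10,000 Monte Carlo
iterations and n = 10,000 parameter-recovery fits per family;
family-selection checks on synthetic study sets use 200 studies (~600
samples) across 5 seeds; literature-scale checks use the printed study
counts. These sizes keep the full suite under a few minutes on one CPU
while leaving Monte Carlo standard errors far below the asserted margins.
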