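---
title: "Assemblage-based SST transfer functions for reef corals: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assemblage-based SST transfer functions for reef corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative low-latitude paleotemperature records are scarce, yet reef
corals leave an abundant fossil record. If the *composition* of a coral
assemblage is controlled by the thermal regime of the surrounding water,
then a mapping calibrated from modern assemblages to modern sea-surface
temperature (SST) can be inverted on fossil assemblages to estimate past
SST. `coralclim` implements this programme end to end: occurrence records
are filtered to the shallow, zooxanthellate reef fauna, binned into
1-degree cells as proportional compositions, calibrated against a monthly
SST climatology by two independent transfer-function families, and the
calibrated models are projected onto Last Interglacial (LIG) assemblages to
yield latitudinal anomaly profiles. Two environmental targets are handled
throughout: mean annual SST and the seasonal temperature variability (STV),
defined as the warmest-month minus coldest-month climatological mean.

Because the real occurrence and climate archives are large external
downloads, the package ships a fully synthetic *species-niche world* with a
known imposed anomaly. Every claim the test suite makes about recovery
skill is made against that ground truth.

## Data preparation

* **Filters.** Depth at most 60 m (boundary inclusive) and zooxanthellate
  taxa only. Records with missing depth are retained with a warning
  (occurrence-database depth fields are sparse; dropping them would discard
  most real data); a switch drops them instead.
* **Gridding.** Cells are 1-degree boxes with floor semantics; longitudes
  are normalized to [-180, 180). Proportions are count-based — a taxon's
  share of all occurrence records in the cell — rather than
  presence/absence, with a presence/absence mode for robustness checks.
* **Cell exclusion.** Cells occupied by a single genus are excluded: such
  cells typically reflect a taxonomic sampling focus, not community
  composition. We apply the rule to both the factor-analysis and the
  network branch, and to modern and fossil matrices alike (symmetric
  treatment; the motivating bias is method-agnostic).
* **Harmonization.** Modern and fossil matrices are restricted to their
  shared taxon pool, rows renormalized, and the genus-richness filter
  re-applied.

## Imbrie–Kipp factor-analysis transfer function (IKFA)

The classic micropaleontological recipe, implemented from first principles:

1. each assemblage row is scaled to unit Euclidean length (Q-mode), so that
   factors represent end-member assemblages;
2. the scaled matrix `W` is decomposed by SVD and truncated at rank `k`,
   `W ≈ L Fᵀ` with orthonormal taxon scores `F`;
3. the sample loadings `L` are varimax-rotated (raw Kaiser criterion,
   pairwise planar sweeps with closed-form angles);
4. the environmental variable is regressed on the rotated loadings by least
   squares, optionally with squared and cross terms.

Fossil rows are aligned to the calibration taxon order with structural
zeros, unit-scaled, projected onto the taxon scores, and passed through the
regression. The *communality* — the fraction of a scaled row's squared norm
captured by the retained factors — flags no-analog assemblages (default
threshold 0.5); flagged cells are kept in outputs but marked.

Numerical conventions worth knowing:

* The regression absorbs any orthogonal rotation of the factor basis, so
  calibration predictions are rotation-invariant (checked numerically in
  the tests); rotation matters only for interpretation and serialization.
* Factor sign/order are canonicalized (columns by explained variance, sign
  so the largest-magnitude taxon score is positive), making serialized
  models reproducible.
* `k` defaults to 5 and is selectable 2–8; the analysis driver selects it
  by minimum leave-one-out RMSE, the standard practice when the source
  method leaves the count unstated. Quadratic regression terms are off by
  default.
* Aliased regression terms (possible with quadratic terms on low-rank
  data) are treated as zero coefficients at prediction time.

## Neural-network ensemble

A single-hidden-layer feed-forward regression: logistic hidden units,
linear output, squared-error loss minimized by BFGS quasi-Newton iteration
(the loss and analytic gradient are compiled; the optimizer is R's own
`vmmin`). The architecture is capped at 5 hidden units and a total weight
budget — `(p+1)·5 + 6` weights for `p` input taxa, i.e. 946 weights for a
187-species calibration (cap 1000) and 341 for 66 genera (cap 400).
Method descriptions in this literature sometimes say "hidden layers" where
hidden *units* are meant; we use 5 hidden units in one hidden layer — the
conventional weight caps match the single-hidden-layer formula almost
exactly, and `nnet`, the implementation such studies cite, supports
exactly one hidden layer. A deep variant is out of scope.

Many replicates are trained, differing only in their seeded uniform
[-0.5, 0.5] initial weights (a bootstrap-resampling mode exists, off by
default), and the ensemble prediction is the per-cell **median** across
replicates — robust to replicates stuck in poor local minima. Inputs and
the output are standardized internally; constants are stored with the
replicates. Convergence uses an absolute tolerance of 1e-4 on the
standardized squared error plus a relative tolerance of 1e-8, mirroring the
referenced implementation's stopping rule; both are configurable (the exact
interpolation tests tighten them). Replicates that fail to converge are
dropped from the median with a recorded count; a run fails when more than
20% fail.

## Anomalies and comparison statistics

Anomalies are reconstructed-fossil minus *observed modern climatology* at
the same cell — the less circular baseline (a model-vs-model comparison is
available by supplying modelled modern values as the reference field).
Latitudinal profiles are smoothed by LOESS (tricube weights, span 0.8,
local degree 2, via `stats::loess` with exact direct fitting) and
summarized as 5-degree band means anchored at multiples of 5. Cross-source
comparison uses Spearman rank correlations on band means (reported as a
matrix with rho lower-left and p upper-right), one-way ANOVA across
sources, and pairwise Wilcoxon signed-rank tests on band-matched pairs,
restricted to 32°S–33°N. P-values are reported raw, without multiple-test
correction, matching the conventional presentation of such tables; the
band is configurable. Identical paired series short-circuit to p = 1
(the signed-rank statistic is undefined on all-zero differences). The
ANOVA's unit of replication is the band mean — a deliberate choice where
the source leaves the design unstated, consistent with the band-based
correlation table.

## The synthetic world

The generator emulates the features that matter for an assemblage-based
thermometer and nothing else:

* a 1-degree ocean from 35°S to 35°N (two longitude columns; 140 cells),
  mean SST 28 °C at the equator declining 0.25 °C per degree of latitude;
* sinusoidal monthly seasonality in hemispheric antiphase, with annual
  range 1 °C at the equator rising by 1/6 °C per degree (6 °C at 30°);
* 30 species in 10 genera; 80% have Gaussian occupancy responses to mean
  SST (optima spread over 18–30 °C, tolerances 1.5–4 °C, peaks 0.3–0.9) and
  20% increase monotonically with SST — mirroring the empirical pattern
  that most coral taxa's occupancy declines toward the warmest water while
  a minority of families shows positive correlations;
* binomial detection: `Binomial(effort, p)` per cell and taxon with
  `p` the niche's occupancy probability at the cell's mean SST; modern
  effort 50 visits per cell, depths uniform on (0, 60] m so the depth
  filter is exercised but passes (a contamination fraction deeper than
  60 m is injectable to test it);
* a fossil scenario sampled at effort 10 over 60% of cells from a field
  shifted by the imposed anomaly: −1 °C within 15° of the equator, +2 °C
  poleward of 25°, linear in between, mimicking the sparsity contrast of
  real archives (thousands of fossil records against hundreds of
  thousands of modern ones).

What it deliberately does **not** emulate: ocean dynamics, coastlines and
land cells, dispersal limitation, non-thermal habitat factors, taxonomic
error, and time averaging of the fossil record. Passing recovery tests on
this world therefore demonstrates that the *pipeline machinery* is
correct and that the statistical method can invert a clean
niche–temperature signal at realistic sparsity — not that real coral
occurrences carry so clean a signal. One consequence of temperature being
the only niche axis: reconstructed STV anomalies partly mirror mean-SST
anomalies (both are functions of |latitude| here), so STV recovery is not
independently diagnostic in the synthetic world.

## Problem sizes and seeds

The shipped analyses and tests run at desk scale, chosen once: recovery
checks use the 140-cell world (seed 42) or a 120-cell variant for
leave-one-out experiments; ensembles use 1000 replicates in the analysis
drivers, 100 for leave-one-out cross-validation, and 20–30 inside repeated
seeded experiments, with the replicate count always recorded in the
output. All randomness flows from explicit integer seeds through a single
derivation function, so every table in `results/` is bit-reproducible.

## Known limitations

* The IKFA regression is linear in the loadings by default; strongly
  nonlinear niche–environment structure is left to the network branch (or
  the quadratic flag).
* Communality-based no-analog screening flags but does not exclude; users
  of real fossil data should inspect flagged cells.
* Leave-one-out for the network ensemble retrains every replicate per
  held-out cell; at the shipped sizes this is minutes of CPU, and it grows
  linearly with cells × replicates.
* Real-data ingestion expects pre-resolved taxonomy (a user-supplied
  synonym table); no name-resolution service is consulted.
* Gridded SST is ingested from long-format CSV; the climatology drops
  cells with any missing climatological month rather than infilling.
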