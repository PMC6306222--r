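---
title: "Methods: climate-envelope forecasting and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-envelope forecasting and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtraj)
```

## The model

`envtraj` treats vegetation as a categorical response of climate. The
climate envelope of each of K vegetation communities is estimated by an
ensemble of classification trees: per cell, predictors are the values of
the bioclimatic layers, the response is the majority-area vegetation class.
Forecasting projects the fitted envelope onto perturbed climate surfaces
and reads off, per cell, the fraction of trees voting for each class — a
*relative likelihood* vector in `[0, 1]^K` summing to one.

Two assumptions are load-bearing and inherited from the climate-envelope
tradition. First, niche stability: the statistical association between
climate and community composition estimated from the baseline period is
assumed to hold under future climates, ignoring disturbance history,
edaphic constraints, dispersal limits and novel competition. Second,
equilibrium interpretation: a forecast class is the state a cell would
*eventually* reach if its climate persisted, not a dated prediction.
The package's uncertainty products (agreement, diversity, transitions,
trajectory spread across scenario outputs) quantify disagreement *between
climate futures*, not the error of either assumption.

### Ensemble details

- **Trees**: `n_trees = 200` classification trees (the response is
  categorical; tree induction is backed by `ranger`). Collinear
  predictors are retained — tree ensembles do not require
  non-collinearity, and correlation structure changes under forecast
  climates anyway.
- **Subsampling**: each tree trains on a seeded random `1 - holdout`
  (default 80%) subsample drawn *without replacement*; the excluded 20%
  accumulates the out-of-bag (OOB) misclassification estimate. Classical
  bootstrap resampling is available via `replace = TRUE`.
- **Importance**: mean impurity (Gini) decrease, ties broken by variable
  order. With box niches carved along particular variables, those
  variables occupy the top ranks (tested).
- **Likelihoods**: vote fractions, not averaged per-tree probabilities.
  The per-cell argmax is invariant under any strictly monotone rescaling
  of votes, so downstream assignments do not depend on this choice; the
  likelihood *values* feeding the legacy rule do, which is why the choice
  is fixed and documented.
- **Null reference**: uniform random assignment among K classes has
  expected misclassification `(K - 1)/K` — 90% for K = 10 — independent
  of the true class frequencies, since the uniform draw hits the truth
  with probability 1/K whatever the truth is.

## Assignment rules

Per time step the M scenario likelihood maps are averaged cell-wise
(means of normalised vectors are normalised; nothing is re-normalised).
Two assignment rules are provided:

- **argmax** — the class with the largest component; ties go to the
  smallest class index, deterministically.
- **legacy threshold** — the historical class is retained wherever *its
  own* likelihood component is strictly greater than `1/K` (0.1 for ten
  classes), else argmax. Strictness at the boundary follows the rule's
  definition ("greater than"); a component exactly at `1/K` does not
  retain. The alternative reading — comparing the *cell's maximum*
  component to the threshold — would make the rule vacuous (the maximum
  of a normalised K-vector is always ≥ 1/K), so the historical-component
  reading is implemented. Consequently legacy and argmax assignments
  differ exactly on cells where the historical class is not the argmax
  *and* its component exceeds the threshold, a set that shrinks
  monotonically as the threshold rises and is empty at threshold ≥ 1
  (both properties are tested).

## Uncertainty and trajectory products

- **Agreement** — per cell, the modal vote count across the M per-output
  argmax maps (range 1..M). This is computed from the individual outputs,
  not from the averaged map, so "M outputs converged" means literally
  that; the averaged-map argmax can differ from the modal class in
  principle. Diversity is the distinct-class count; `diversity == 1` iff
  `agreement == M`.
- **Transitions** — per cell, the number of consecutive class changes
  along the ordered series (baseline map, then the per-time-step
  ensemble-average argmax maps): 0–3 for four time points.
- **Trajectory table** — per class: baseline hectares (cell count ×
  `cell_area_ha`, default 100 ha for 1-km cells) against min/mean/max
  hectares across the M final-time-step outputs. Trend is `-` iff
  `max < baseline`, `+` iff `min > baseline`, else `unk`. Boundary
  equality is classified `unk`: a forecast range that merely *touches*
  the baseline is not evidence of direction. A class absent from an
  output contributes 0 ha there, which is what an absent forecast means.

## The synthetic landscape

The generator exists so that every downstream stage can be tested against
known truth; its defaults define the package's reference conditions.

- **Climate fields**: per variable, `baseline_mean` + a centred linear
  gradient (total change `grad_row`/`grad_col` across the grid) +
  Gaussian-filtered white noise rescaled to `noise_amplitude` and
  mean-centred, then clamped at `lower`. Centring makes the regional mean
  equal the configured baseline exactly, which keeps summary tables
  interpretable; it is the simplest field with tunable autocorrelation
  (`correlation_length`, in cells). The shipped default emulates a
  maritime–continental subarctic region: MAT 1.9 °C, MAP 1735 mm,
  PAS 862 mm, Eref 351 mm, with AHM = (MAT + 10)/(MAP/1000) derived per
  cell rather than simulated. Note the regional mean of per-cell AHM is
  not the AHM of the regional means (Jensen's inequality), so summary
  tables report the former.
- **Vegetation**: box niches (`niche_rule`) evaluated on bilinearly
  interpolated climate at `fine_factor`× resolution. Intervals are
  half-open `[low, high)` so adjacent niches partition cleanly along a
  shared threshold; overlaps resolve by unique priority; a boundless rule
  is the fallback; uncovered climate is an error, not a silent class.
  Label noise flips each pixel independently to a uniformly drawn *other*
  class, so the expected disagreement with truth is exactly the noise
  rate — an analytically checkable target (tested at ±2%).
- **Scenarios**: each variable is scaled per cell by `1 + delta`. The six
  default 2080s outputs are three GCM exposure levels (low INM-CM4, mid
  15-GCM average, high GFDL-CM3) × RCP 4.5/8.5; their deltas are the
  package's reference percent changes (e.g. GFDL-CM3 RCP 8.5: AHM +26%,
  PAS −76%, MAP +28%, Eref +37%, MAT +365%). Earlier time steps use 1/3
  and 2/3 of the 2080s delta — a linear ramp that preserves scenario
  ordering, chosen because only end-of-century changes are specified.
  Derived AHM is recomputed from the perturbed MAT and MAP rather than
  scaled independently, keeping each scenario surface internally
  consistent.

What the generator does *not* emulate: mixed pixels and sensor error of a
real supervised classification (label noise is spatially white, real
error is structured), topographic complexity (fields are smooth
gradients), non-box niches, and disequilibrium vegetation dynamics. A
passing pipeline on this landscape validates the *machinery* — rescaling
arithmetic, vote bookkeeping, assignment rules, area accounting — and the
recoverability of a strong climate signal. It does not validate that real
vegetation is predictable from climate: with cleanly separable synthetic
niches the OOB error is near zero, whereas real landscapes with
interspersed communities sit far higher, approaching the `(K−1)/K` null
as the signal vanishes (the permuted-label test checks that limit).

### The trajectory-recovery configuration

`box_recovery_config()` is a purpose-built 100×100 landscape for testing
end-to-end signal recovery. Scenario deltas are multiplicative, which
constrains the design: temperature must be strictly positive (a negative
MAT cell would get *colder* under a positive delta), and the niche band
receiving displaced cells must be geometrically wide. With MAT spanning
~0.5–4.5 °C and 2080s warming factors of 2.13–4.65, every cell of the
Cold niche (MAT < 0.7) lands inside the broad Mild band ([0.7, 3.9)) with
margin under *every* output, while no future cell remains below 0.7. The
pipeline should therefore report trend `-` for Cold with near-total
six-output agreement over its former extent, and `+` for Warm
(MAT ≥ 3.9), whose niche only gains cells. Label noise is 0 here: the
configuration isolates the climate signal; classification error is
exercised elsewhere.

## Numerical and I/O choices

- Ties: argmax and majority assignments break ties by smallest class
  index — deterministic and order-stable.
- Rescaling computes fractions over *classified* fine pixels only and
  requires ≥ 1 classified pixel per cell, so unclassified area (water,
  cloud) does not dilute majorities; "percent area" averages over cells
  assigned to the class, and a never-assigned class is reported missing,
  not zero.
- Thresholds are inclusive where defined as such: co-occurrence at
  ≥ 10% of cell area, misclassification share at ≥ 20%.
- Rasters are ESRI ASCII grids (plain text, north-up); floats are written
  with 17 significant digits so round trips are exact at double
  precision; categorical rasters carry a sidecar `_classes.csv` code
  table. Cell ids are 0-based row-major; the convention is recorded in
  every run manifest.
- Determinism: every stochastic step is a pure function of its inputs and
  an explicit seed (`ranger` runs single-threaded with a fixed seed);
  two pipeline runs with one configuration are byte-identical, and the
  manifest stores the seeds and file hashes needed to re-create a run.

## Problem sizes

The shipped demonstration configuration uses a 40×40-cell climate grid
with a 200×200 fine vegetation map, ten classes, 200 trees and eighteen
scenario surfaces (completing in seconds); the recovery analysis uses
100×100 cells. These sizes keep test suites fast while leaving every
per-cell statistic well resolved; all operations are linear in cell count
and have been run comfortably at several hundred thousand cells.

## Known limitations

- Likelihoods are vote fractions, not calibrated probabilities; the
  legacy threshold compares them to `1/K` as a relative, not
  probabilistic, criterion.
- Scenario outputs are weighted equally in averages and agreement; there
  is no skill weighting.
- Percent-change deltas are multiplicative, which is natural for
  precipitation-like quantities but scale-dependent for temperature
  (a percent of °C depends on the zero point); the generator applies
  them as given and therefore requires positive-valued fields where
  niche contraction arguments rely on monotone displacement.
- The agreement map defaults to per-output argmax assignments; computing
  it from threshold-mediated maps is possible by passing those maps to
  `agreement_map()` directly.
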