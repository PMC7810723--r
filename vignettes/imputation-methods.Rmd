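---
title: "Plot imputation by terminal-node co-occurrence: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot imputation by terminal-node co-occurrence: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plotimpute` assigns a forest-inventory plot identifier to every forested
pixel of a gridded landscape. This vignette is the package's account of the
method: the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where the method description leaves room.

## The imputation model

Two data sets enter: *reference* data (inventory plots with derived cover bin,
height bin and vegetation group, plus location, topography, six biophysical
values and disturbance code/year) and *target* data (the same variables as
wall-to-wall rasters). For each of the three response variables the engine
grows `trees_per_response = 83` classification trees — 249 in total — on the
reference plots:

* each tree sees a 66% subsample of plots drawn **without replacement**
  (`bootstrap_fraction = 0.66`); the phrasing "66% of the observations are
  randomly chosen" describes subsampling, not classical with-replacement
  bagging, and the remaining 34% score the out-of-bag (OOB) error;
* at each node `mtry = floor(sqrt(p))` candidate variables are drawn; the
  split minimising Gini impurity of the response is applied;
* splitting stops when a node is pure or when any resulting bucket would hold
  fewer than `min_bucket = 5` plots.

A pixel is imputed by running its variable vector down all 249 trees and
counting, per reference plot, the trees in which the pixel and the (in-bag)
plot share a terminal bucket. The modal plot wins; exact ties are broken
uniformly at random under the run seed. The responses are not predicted
directly — the forest is a learned similarity, and the vote identifies the
most similar plot.

**Response variables route pixels.** The response surfaces exist for target
pixels just as for plots, and with
`responses_as_split_candidates = TRUE` (default) they join the predictors as
split candidates in all three forests, including the forest labelled by that
same response. This is deliberate: matching a pixel's observed cover bin is
the point of the method, and it is what produces OOB errors orders of
magnitude below what topography alone could achieve (a plot routed by its own
response lands in a bucket pure in that response). Setting the flag to `FALSE`
gives the classical predictor-only formulation; both are supported because
descriptions of this family of imputations are ambiguous on the point, and the
two behave very differently on weakly structured landscapes.

Key assumptions: every vegetation group present on the masked landscape has at
least one reference plot (enforced, with an error naming the offending class —
the preprocessing recode table exists to fix exactly this); rasters are
exactly co-registered (alignment is checked by equality, never resampled); at
most `max_classes_per_run = 32` vegetation groups per run, with zonal
processing (`run_zonal()`) as the supported way to handle richer landscapes.

## Preprocessing rules

* **Cover bins.** Forest is cover ≥ 10%. Bins are 10 points wide with midpoint
  recoding (15 … 95), half-open `[lo, hi)`, bottom edge inclusive, top bin
  closed at 100%. Whether the threshold applies to raw percent or to the
  binned class is undocumented in the source material; the package applies bin
  membership (the lowest forest bin is 10–20%), which is equivalent for any
  input that is already binned.
* **Height bins.** 0–5 → 3, 5–10 → 8, 10–25 → 18, 25–50 → 38, ≥ 50 → 70 m;
  edges belong to the upper bin.
* **Disturbance collapse.** Annual layers (fire = 1, insect/disease = 2)
  reduce to one code/year pair per pixel: any fire wins over any
  insect/disease regardless of order; within a type the most recent year is
  kept. Undisturbed pixels carry the sentinel pair (0, 0) — the year sentinel
  is 0 rather than `NA` so the band stays numeric for tree splits and is
  unambiguous against the valid years. The identical rule reduces the plots'
  three disturbance slots.
* **Vegetation-group recode.** A two-column CSV maps source codes to targets
  or `DROP`; the shipped default carries the national 2014 substitutions
  (692→693, 705→668, 649 and 730 dropped). Chained substitutions are rejected.
* **Centroids.** Pixel centres are computed in the projected CRS and converted
  to latitude/longitude. Without PROJ bindings the package supports
  `crs_geographic()` and a spherical local azimuthal-equidistant projection
  (`crs_aeqd()`), verified in tests against an independent geodesic oracle to
  below 1e-9 degrees. Real-world stacks in other projections need their
  lat/lon bands supplied directly.

## Plot-level derivations

* **Canopy cover** uses the random-placement overlap correction
  `C = 100 (1 − exp(−A))`, `A = Σ π r_i² tpa_i / unit_area` over live trees.
  `unit_area` is the ground area the trees-per-area expansion factor refers to
  (10,000 m² for per-hectare factors, 4,046.86 m² for per-acre); it is a
  parameter because inventory systems mix unit conventions. Crown radii are a
  required input column; the allometric machinery that would derive them from
  species and diameter is external software and out of scope.
* **Top-stratum height** sorts live-tree heights ascending, anchors at rank
  `ceiling(0.7 n)` and averages the nine ranks centred there, clipped to the
  list ends; plots with fewer than nine live trees average all. The anchor
  definition and clipping are package choices — the upstream description names
  neither — as is interpreting the percentile over trees rather than
  basal-area-weighted trees. The full stratum-splitting behaviour of stand
  classifiers (gap detection between canopy layers) is deliberately not
  reproduced; this single-top-stratum rule is a stated fidelity limit.
* **Dominant species** are the two highest per-species basal areas
  `Σ π (d/2)² tpa` over live trees; exact ties break by ascending species
  code (any fixed order would do; this one is reproducible from data alone).

## Accuracy assessment

Confusion matrices are oriented rows = imputed, columns = target; user's
accuracy is diagonal over row total, producer's over column total, and two
algebraic identities (overall equals the row-weighted mean of user's and the
column-weighted mean of producer's accuracies) are asserted in tests on every
matrix. Footprint validation examines pixels whose centroid falls within
40.25 m of a validation plot (the splayed four-subplot inventory footprint):
any-match flags compare bins; "weighted" cover/height are equal-weight means
over the footprint pixels — the upstream description says "weighted" without
defining weights, and centroid-in-radius pixels have no natural unequal
weighting — with tolerances of 10 cover points (one bin width, i.e. "within
10%" read as percentage points, consistent with 10-point bins) and 5 m.
Plots with no forested footprint pixel leave the denominator and are counted
separately. Percent summaries round half-up to one decimal, matching the
published table style.

The standing-dead analysis compares per-plot standing-dead counts between
burned (and separately infested) and undisturbed plots with a two-sample
Kolmogorov–Smirnov test. The p-value uses the asymptotic Kolmogorov series
(100 terms) at `t = sqrt(n_a n_b / (n_a + n_b)) · D`; below `t = 0.05` the
truncated series is numerically unreliable and the tail probability is 1 to
more than 100 decimal places, so 1 is returned. Exact small-sample p-values
are out of scope at the sample sizes this analysis targets; the tests
cross-check against `stats::ks.test(exact = FALSE)` and verify null
calibration with unequal sample sizes (with equal sizes the statistic lives on
a lattice and p-values are visibly discrete).

## The synthetic generator

`generate_landscape()` + `generate_plots()` produce a landscape with known
ground truth: smooth biophysical and topographic surfaces (white noise
convolved with a squared-exponential kernel; `corr_length = 10` pixels),
blocky vegetation-group regions (nearest of three seeded patches per class),
a non-forest margin, and a plot network in which every pixel descends from its
nearest same-group plot. Pixel cover/height are the generating plot's values
plus Gaussian noise, then binned — so at zero noise every pixel's bins equal
its generating plot's bins exactly, which the tests assert. Tree lists are
constructed so the derived attributes land exactly on the plot's values:
heights are scaled so the nine-tree rule returns the plot height, crown radii
so the overlap-corrected cover equals the plot cover (a rejection-sampling
retry budget guards the construction). Disturbed plots receive additive
Poisson extra standing-dead trees (means 5 for fire, 3 for insect/disease over
a baseline of 2), and some burned plots carry a second, superseded
insect/disease record so the fire-precedence rule is exercised end to end.

Chosen study conditions, stated once: plot cover and height descend from
smooth landscape surfaces (twice the biophysical correlation length) plus a
group offset, because canopy structure on real landscapes tracks environmental
gradients — independent draws per plot would make the response surfaces
spatially unpredictable in a way real classified vegetation products are not.
Attribute noise defaults to 15% of the narrowest bin width (1.5 cover points,
0.75 m of height): classified rasters are blocky, and within-stand
bin-crossing beyond ~10% of pixels would not emulate them. Disturbance rates
(5% fire, 8% insect/disease) mirror the rough proportions of a national plot
network. The default fixture is desk-scale — 200 × 200 pixels, 500 plots, 12
vegetation groups, 249 trees — chosen so the full pipeline runs in well under
a minute on one CPU; tests use smaller grids (40–100 pixels a side) where the
property under test does not need the full fixture.

What the generator does **not** emulate: classification error structure of
real vegetation products (confusions between spectrally similar classes),
plot location error or deliberate coordinate fuzzing, multi-condition plot
heterogeneity (validation plots are simply flagged multi-condition), irregular
plot density, and any real geography. Passing recovery tests therefore show
the engine recovers structure it is pointed at — they do not certify accuracy
on real landscapes, where target-data error dominates.

## Numerical and degenerate-input choices

* Determinism: one seed per run, forked into named substreams per stage
  (`rng_substream_seed()`), so a stage rerun in isolation reproduces its
  in-pipeline result; identical inputs and seed give bit-identical maps.
* Split-gain ties resolve to the first candidate in fixed variable order and
  the smallest threshold; numeric thresholds are midpoints of adjacent
  observed values; categorical splits order levels by within-level frequency
  of the node's majority class and scan that ordering greedily.
* An unseen categorical level at prediction routes to the child that held more
  in-bag plots (and is exercised in tests); leaf class ties resolve to the
  smallest label.
* The co-occurrence tally counts in-bag plots only: out-of-bag plots have no
  defined terminal bucket in their own tree's partition. Every tree weighs
  equally; no normalisation by bucket size.
* A single reference plot yields one-leaf trees, an imputation that assigns it
  everywhere, and an OOB error reported as 0 with a warning (it is undefined).
* Degenerate inputs error early and by name: misaligned rasters, vegetation
  groups without plots, standing-dead flags on live trees, disturbance years
  without codes, negative heights, empty Kolmogorov–Smirnov samples.

## Known limitations

The engine is pure R; at the default desk scale a full chain runs in seconds,
but it is not sized for continental rasters (the published national runs this
package re-implements used dedicated infrastructure and zonal parallelism).
Raster I/O is ASCII-grid-with-manifest, adequate for the text-based formats
this package targets but not a GeoTIFF reader; CRS support covers geographic
and local azimuthal-equidistant grids only. The reference implementation of
stand structure classification (multi-stratum gap detection, allometric crown
radii) is intentionally simplified to the two documented behaviours, and the
32-class limit is honoured rather than worked around, zonation being the
supported remedy.
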