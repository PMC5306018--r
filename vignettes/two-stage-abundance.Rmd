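---
title: "Two-stage occupancy-to-abundance modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage occupancy-to-abundance modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occAbund)
```

## The problem

Occurrence records for plants are plentiful — botanical atlases hold
millions of presence-only observations at coarse grid resolution — while
abundance measurements (percent cover) are scarce, heterogeneous and
heavily zero-inflated. `occAbund` implements a two-stage method that
leverages the former to stretch the latter: ensemble species distribution
models (SDMs) fitted to presence–absence data yield per-species occupancy
probability maps, and those maps (for *all* species, not just the focal
one) plus four tree-cover covariates feed a random-forest regression that
predicts percent-cover abundance on a 1-km grid.

Because real atlas and survey data cannot be redistributed, the package
ships a virtual-species simulator that reproduces the statistical structure
both stages assume, so every claim the package makes is testable against a
known generating truth.

## Stage 1: from presence-only records to occupancy maps

**Presence–absence derivation.** Occurrence records carry a spatial
precision class. Records coarser than the tetrad (2 × 2 km) are discarded;
finer records are re-keyed to their containing tetrad; duplicates collapse.
Inferred absences require evidence of effort: a tetrad is *well surveyed*
when at least 2 surveys in the 1950–2014 window (endpoints inclusive) each
recorded at least 50 plant species. Well-surveyed tetrads without a record
of the focal species become absences. A deliberate asymmetry: tetrads
*failing* the effort criterion but holding a record are kept as presences
(a record is evidence regardless of effort), while their record-free cells
stay unknown rather than becoming absences. Where a survey log mixes
qualifying and weak surveys, weak surveys are simply not counted — they do
not disqualify a tetrad. This reading of "each survey" is an
interpretation; the monotonicity property (raising the species threshold
never enlarges the well-surveyed set) holds under it.

**Covariate pruning.** Within every pair of continuous covariate layers
with pairwise Pearson |r| strictly above 0.7 one layer is removed. The
published rule keeps "variables known to be important"; we encode that
knowledge as explicit per-layer priority ranks and resolve violations
greedily from the most collinear pair down, dropping the lower-priority
member. Greedy resolution is deterministic, idempotent, and for small
stacks agrees with exhaustive subset search; priorities are user
configuration because no canonical ordering exists. Categorical layers
never enter the correlation computation; constant layers are excluded with
a warning rather than treated as correlated.

**The six-family ensemble.** Each species is fitted with six algorithm
families — GLM, GAM (spline-basis additive logistic model), CTA (single
classification tree), GBM (gradient-boosted trees), RF (probability random
forest) and a MaxEnt-like member — on `repeats` (default 15) random 70/30
splits, unstratified, with split seeds `seed + repeat`. Since the training
input here is presence–absence rather than presence–background, the MaxEnt
slot is filled by a penalized logistic regression on an expanded feature
basis (linear, quadratic and pairwise-product terms), which preserves the
flexible-response character of MaxEnt without its background-sampling
machinery; it is named `maxent_like` to make the substitution explicit.
Default hyperparameters: RF 500 trees, GBM 100 trees of depth 3 with
learning rate 0.1, CTA complexity 0.01, GAM basis dimension 5. On very
small training sets the GAM smoothness search can fail numerically; the
fit then retries with a smaller basis and finally degrades to the additive
linear logistic limit instead of erroring. Nonsignificant covariates are
never removed.

**Scoring and selection.** Each fit is scored on its held-out 30% by ROC
AUC (pair-counting definition, ties half) and the true skill statistic
(TSS = sensitivity + specificity − 1, maximized over the midpoints of
consecutive sorted unique predictions plus the endpoint values; the
smallest optimizing threshold is reported on ties). If a leading group of
models is separated from the remainder by a gap of at least 0.05 in *both*
ROC and TSS (the published rule is qualitative — "a step higher" — and
0.05 is our numeric reading), the smallest such group is selected;
otherwise the top 20 by ROC, ties at the cut included. A consensus filter
then replaces the published manual response-curve screening: members whose
predicted map deviates from the cellwise median map by more than 0.25 mean
absolute deviation are rejected, worst first, never below two survivors.
Automating this step trades expert judgement for reproducibility; response
curves remain exportable (`responseCurves()`) for manual inspection but are
not auto-filtered.

**Ensemble and prediction.** Survivors are refitted on 100% of the data
(selection scores still come from the 70/30 runs, so the refit does not
contaminate them) and combined with weights proportional to held-out ROC,
normalized to sum to one. Proportional weighting is adopted from the
method's own description; some ensemble platforms apply a decay transform
instead, which we deliberately do not. The occupancy map is the weighted
mean of member predictions per 1-km cell — a convex combination, hence
always within [0, 1] — with missing covariates propagating to no-data.

## Harmonizing abundance surveys

Abundance is expressed as hectares covered by the species per km², which
is numerically percent cover of the cell. Two survey dialects convert
exactly:

* patch dialect (woodland-survey style): within-patch percent cover ×
  woodland fraction of the cell;
* plot dialect (countryside-survey style): linear-plot percent × linear
  feature fraction + areal-plot percent × remaining fraction — a convex
  combination of the two plot percentages.

Both are exact closed forms; outputs are clipped to [0, 100] only to guard
floating-point overshoot. Records in cells lacking the required layer
value are dropped with a count; multiple records per (species, cell) are
kept as independent rows, since no published reconciliation rule exists —
an interpretation, flagged here.

The woodland-edge covariate C_E is the fraction of each 1-km cell that is
woodland within 50 m of nonwoodland, computed on a fine binary mask
(default 10-m cells) by exact Euclidean centre-to-centre offsets — a disc
dilation of the nonwoodland mask intersected with woodland — and block
aggregation. It agrees with a brute-force per-cell nearest-nonwoodland
scan on every grid up to 64 × 64 in the test suite. All-woodland and
all-nonwoodland masks yield zero edge by definition, not an error. The
other cover layers satisfy C_A = C_W + C_O wherever defined.

## Stage 2: the abundance forest

For focal species *f*, the design matrix has the focal occupancy
prediction first, every other species' prediction in sorted name order,
then C_A, C_W, C_O, C_E — with *n* species, *n* + 4 columns. Including all
species' occupancy lets the forest pick up interspecific signal such as
competitive suppression; the simulator writes such signal into its truth
so the tests can confirm the competitor's map ranks highly in permutation
importance.

The regression is a bagged tree ensemble (500 trees, a third of the
covariates per split, permutation importance recorded at fit time),
deterministic under its seed. Tree averaging interpolates, so predictions
cannot exceed the maximum observed abundance and are clipped at zero.

**Fold rule.** Cross-validation is k-fold with k = 10 when at least 50
nonzero records exist (an average of five nonzero records per fold),
k = floor(nonzero/5) below that, and refusal — the species is reported,
not modelled — below 30 nonzero records. The published practice fitted a
species at 42 nonzero points (8 folds) and refused species with 27 or
fewer; 30 splits the undecided interval and is configurable. Fold
assignment is random and unstratified, seed recorded. RMSE and MAE are
reported per fold and pooled, in response units. R² (1 − SSE/SST on pooled
held-out predictions; can be negative) is always accompanied by a caveat
flag: with zero-inflated abundance the zero mass dominates SST and R²
understates a model that predicts "slightly above zero" for true zeros.
RMSE/MAE are the headline metrics. An optional cutoff coercing small
predicted abundances to zero is available but off by default — choosing it
is a user decision, not a package default.

## The virtual-species simulator

The generator's role is to emulate the statistical structure the method
assumes, with full knowledge of truth:

* **Environment:** spatially autocorrelated standardized Gaussian fields
  (white noise convolved with a Gaussian kernel on a torus via FFT — exact
  stationarity, lag correlation monotone in the range parameter), plus a
  categorical habitat layer from quartile bins of a further field.
* **Occupancy:** per species, logistic in the continuous covariates with
  coefficients at scale `betaSd` (default 2 — a strong environmental
  signal) and intercept calibrated by root-finding so mean occupancy hits
  a target prevalence drawn from 0.3–0.55. Realized presence is a
  Bernoulli draw per cell.
* **Abundance:** zero wherever occupancy is below the floor (default 0.3)
  or the species is absent — a hard-threshold zero inflation that
  reproduces the zero-heavy regime of real percent-cover data (with a high
  floor and low prevalence, over 90% of sampled records are zero) —
  otherwise a monotone power of occupancy above the floor, scaled by total
  tree cover and damped by `exp` of interaction-weighted competitor
  occupancies. Species overlap freely; per-cell sums over species may
  exceed 100.
* **Tree cover:** a fine-scale woodland mask (thresholded Gaussian field,
  ~30% woodland) yields the woodland fraction, C_W (woodland canopy), C_O
  (outside-woodland cover), C_A = C_W + C_O, and C_E via the package's own
  edge computation at 50-m fine cells (the coarsest resolution the 50-m
  edge rule permits; full 10-m masks would be prohibitive at landscape
  scale and change nothing structurally).
* **Surveys:** per tetrad, a Poisson number of botanical surveys (a
  configurable fraction of tetrads receives none — deliberate
  under-surveying), each with a recorded total species count (normal,
  mean 75, sd 20, so a realistic share of surveys fails the 50-species
  bar); occupying species are detected per survey with probability 0.9 by
  default, and records carry a precision-class mix including coarse
  records that the preparation step must discard. The detection
  probability implicit in real atlas data is unknown; this is a free
  parameter of the simulator, not a claim about any dataset.
* **Abundance samples:** noise is applied on the harmonized scale and then
  translated into each dialect, so with zero noise harmonization inverts
  sampling exactly — the property the recovery tests rely on. Patch-dialect
  records are drawn only in wooded cells where the within-patch percentage
  is well defined.

What the simulator does *not* emulate: real geography and climate fields,
spatially structured survey effort (effort is independent of environment),
observer heterogeneity, taxonomic error, or temporal change across the
study window. Passing recovery tests therefore demonstrates the pipeline's
internal correctness and its statistical power under the stated
assumptions — not performance on any real dataset.

## Problem sizes used by the test suite

The suite exercises the bookkeeping claim (25 species × 6 algorithms × 15
repeats = 2,250 logged models) on a 24 × 24 landscape with reduced tree
counts — the count is invariant to hyperparameters — and the recovery
claim on an 80 × 80 landscape (≈1,250 well-surveyed tetrads, ~1,500 usable
rows per species) with 5 species, 4 repeats and 2,500 records per
abundance dialect. Under those conditions every species' ensemble map
scores AUC ≥ 0.8 against the realized presence truth, and the stage-2
forests reach held-out Spearman ρ ≥ 0.8 against the true abundance surface
with pooled MAE below 5 ha/km². Determinism is asserted by hashing every
file of two complete pipeline runs under one seed set.

## Numerical choices and degenerate inputs

* Cell convention: half-open `[x, x + cellsize)` intervals, origin at the
  lower-left corner; a point on a shared edge belongs to the upper cell.
  Tetrads are 2 × 2 blocks of 1-km cells; continuous covariates average
  over the four member cells, categorical covariates take the modal
  category (smallest code on ties).
* TSS threshold ties: the smallest optimizing threshold is reported.
* Single-class labels make ROC and TSS undefined: an error, not NA.
* Factor levels unseen at training time map to the modal training level at
  prediction time, so every member can always predict.
* Gridded text I/O uses the ESRI ASCII grid format with `%.17g` precision,
  making write-read round trips bit-faithful; no GeoTIFF writer is
  included, keeping the package dependency-light and its outputs diffable.
* Configuration round-trips losslessly through YAML; run manifests record
  a config hash and full file list, with no timestamps, so identical runs
  produce identical trees.

## Known limitations

The consensus filter can mistake a genuinely better minority model for a
contrarian; the floor of two survivors bounds but does not remove that
risk. The leading-group gap (0.05) and the consensus threshold (0.25) are
interpretations of qualitative published rules. Proportional ROC weights
give near-uniform weights when member scores are similar. The stage-2
forest cannot extrapolate beyond observed abundance maxima, which is a
feature for percent cover but a limitation for open-ended abundance
measures. Refused species (below 30 nonzero records) produce no map at
all; no fallback estimator is offered.
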