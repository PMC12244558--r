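---
title: "Methods: stacked species distribution modelling with stacksdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked species distribution modelling with stacksdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksdm)
```

## The model

`stacksdm` estimates the species richness of an assemblage from
presence-only occurrence records and gridded environmental predictors by
the stacked species distribution model (S-SDM) recipe: fit one habitat
suitability model per species, binarise each suitability surface into a
predicted range, and sum the binary maps cell by cell. Each per-species
model is an ensemble: several learners of different inductive biases
(classification tree, random forest, RBF support vector machine by
default; logistic GLM with quadratic terms, boosted trees, GAM and a small
neural network are available behind the same adapter contract) are fitted
to presences plus pseudo-absences, and their predictions are averaged with
weights proportional to each member's cross-validated AUC (uniform weights
by configuration). Under ecological niche theory the suitability surface
approximates the projection of the species' niche onto geographic space;
stacking approximates richness as the sum of independent per-species
occupancy indicators.

### Pseudo-absences

Presence-only data require background points. They are drawn without
replacement from valid cells that are not presence cells (optionally
excluding a Chebyshev buffer around presences, default 0), allocated over
a 5 x 5 grid of geographic blocks proportionally to each block's count of
eligible cells, with floor rounding and remainders to the
largest-eligibility blocks. The stratification spreads the background over
the landscape so that large homogeneous areas are not over-represented by
chance. Following the common recommendation, classification-family
learners get as many pseudo-absences as presences while regression-family
learners (GLM/GAM) get 1000; both are configurable and classes are
re-weighted inversely to frequency inside every adapter, so unequal counts
do not tilt the decision surface. Some pseudo-absences inevitably fall
inside the species' true range; this label contamination is the price of
presence-only data and is one reason stacked predictions are noisier than
the per-model AUCs suggest.

### Evaluation and thresholding

Models are evaluated by stratified k-fold cross-validation, k = 20 by
default, repeated 10 times with reshuffled folds. Species with fewer
presences than k get k lowered to the smaller class size (with a message);
this resolves the tension between a fixed k = 20 and species with few
records, which any compilation contains. Each held-out fold is scored at
its own TSS-optimal threshold; reported metrics (AUC, sensitivity,
specificity, omission, proportion correct, Cohen's kappa, TSS, Jaccard)
are means over folds and replicates.

Binarisation thresholds maximise TSS = sensitivity + specificity − 1 over
the candidate set of observed prediction values, with "presence iff
prediction ≥ threshold" and ties broken toward the smallest qualifying
threshold. The scan uses integer pair counts rather than floating-point
sums, so ties are exact. A single fitted model's threshold is selected on
its in-sample predictions. The *ensemble* threshold is recomputed on the
combined predictions at the training cells, where each member contributes
its out-of-fold cross-validation prediction (averaged over replicates)
rather than its refit in-sample prediction. This choice matters: refit
predictions of flexible learners are nearly separable on the training
data, which drags the TSS optimum toward a threshold that is too strict
out of sample and systematically shrinks predicted ranges; out-of-fold
predictions remove that bias. On simulated assemblages (below) the
unbiased threshold visibly raises the richness-recovery correlation
without touching the suitability surfaces.

### Variable importance

Permutation importance: for each predictor, the column is permuted
(10 repetitions) and the raw importance is the mean of one minus the
Pearson correlation between predictions on intact and permuted data — a
model-agnostic measure of how much the prediction field depends on that
variable. Undefined correlations count as zero, negative raw values are
clipped, and the vector is normalised to percentages. The published notion
of "decrease in performance after randomising a variable" is not a
formula; this correlation-loss definition is the package's documented
reading, shared with other SDM ensembles.

### Stacked surfaces and community evaluation

Richness is the cellwise sum of binary ranges. Uncertainty is the
between-algorithm population standard deviation of member suitabilities,
averaged over species — it isolates structural (algorithm) disagreement
rather than replicate noise. Endemism uses the weighted endemism index,
`WEI(cell) = sum_s presence_s(cell) / range_s`, which up-weights
range-restricted species. Community evaluation treats every grid cell with
at least one observed record as a site: observed presence means "recorded
in that cell", and absence of the remaining roster species is assumed —
the convention forced by presence-only data, stated openly because it
makes the specificity and prediction-success figures conventions, not
facts.

### Diversity statistics

Regional contrasts use a classical one-way ANOVA on per-cell richness with
Tukey HSD intervals at 95% family-wise confidence; region polygons are
user-supplied labels (no default partition is bundled, since any regional
split is a modelling choice). Gradients are ordinary least squares of
richness on cell-center latitude or longitude, reporting the slope in
species per unit coordinate with t, R², F and p. Spatial autocorrelation
is global Moran's I with binary rook-contiguity weights, not
row-standardised, with the normality approximation for the z-test; the
expectation is −1/(n−1). Row-standardised or distance-decay weights give
different (sometimes out-of-[−1,1]) values, which is why the weight
specification is stated here and kept fixed.

### Importance-profile clustering

Species are clustered by their ensemble importance profiles: PCA on the
standardised species x variable matrix, then Ward-linkage (`ward.D2`)
agglomerative clustering on the scores of the components explaining at
least 80% of the variance (capped at 5). The number of clusters can be
fixed or chosen automatically as the cut in 2..10 with the largest
relative drop in within-cluster inertia between consecutive cuts. The
classical HCPC consolidation step (k-means refinement after cutting) is
deliberately omitted: it rarely changes well-separated solutions and makes
the assignment depend on initialisation.

## The virtual-species test bed

Real occurrence compilations have no ground truth, so validation uses
simulated scenarios in which everything is known.

* **Landscapes** (`generate_env_stack()`): 15 layers by default, each a
  mixture of a deterministic north-south or east-west ramp (weight 0.25)
  and Gaussian-smoothed white noise (kernel radius 5 cells), rescaled to
  ranges typical of a shallow hypersaline basin (depth −127..−2 m,
  salinity 37.04–37.46, chlorophyll-a 0.73–12.99 mg/m³, and so on). The
  mixture gives each layer both a basin-scale gradient and autocorrelated
  local structure; radius 0 and weight 0 recover pure white noise, which
  the tests use as a Moran's I null.
* **Species** (`define_virtual_species()`): multiplicative Gaussian
  responses on one or two randomly chosen layers (probabilities 0.7/0.3),
  optima uniform within the realised layer range, breadths uniform on
  8–25% of the range, normalised so the best cell scores 1. The true range
  is the top suitability quantile matching a target prevalence drawn
  uniformly from 8–20% of the valid area. The default mix deliberately
  favours simple, separable niches: sixty records per species carry
  enough information to characterise a one- or two-dimensional Gaussian
  niche, and recovery of the known truth is then a sharp test of the
  pipeline rather than of sample size. Higher-dimensional product niches
  can be requested (`niche_layer_probs`), but with ~50 presence cells
  among 15 predictors their ranges are under-determined and the richness
  recovery degrades for reasons unrelated to implementation correctness
  (it stays below target even when thresholds are replaced by oracles).
* **Sampling** (`sample_occurrences()`): 60 draws per species,
  probability proportional to suitability within the true range, then
  deduplicated to cells. Detection is perfect — no false presences and no
  observation noise by default (an optional flip rate exists), so a
  recovery failure indicts the pipeline, not the data.

What the scenario does *not* emulate: a real coastline and bathymetric
mask, spatially biased sampling effort (records cluster near ports and
study areas in real compilations), taxonomic misidentification, and niche
responses that are skewed or bimodal rather than Gaussian. Passing the
recovery tests therefore shows the machinery is correct and well
calibrated under honest conditions; it does not certify performance on a
real, biased compilation.

### Recovery behaviour

On the default scenario (20 species, 15 layers, 100 x 100 grid, 60 records
each) the CTA-RF-SVM pipeline at package defaults reaches a predicted-vs-
true richness Pearson correlation of about 0.85–0.88 across seeds, mean
cross-validated AUC around 0.91, and ranks the true niche layer first in
permutation importance for essentially all single-layer species. Decomposing the
residual error is instructive: binarising the *true* suitability surfaces
at thresholds estimated from the training sample yields r ≈ 0.98, so TSS
thresholding itself is nearly lossless; binarising the *fitted* ensembles
at oracle prevalence thresholds yields r ≈ 0.83–0.85, which is the
model-capability ceiling for ~50 presences per species in 15 predictors.
The shipped pipeline sits essentially at that ceiling; what remains is
attenuation from per-species range misplacement, which more records (not
more tuning) would reduce.

## Numerical choices and degenerate inputs

* Bilinear resampling is conservative about nodata: any contributing
  corner being nodata makes the output cell nodata, so no coastal values
  are fabricated. It is exact for affine surfaces, which the tests assert.
* Pearson correlations between layers use pairwise-complete cells; a
  zero-variance layer yields an explicit undefined row/column with a
  warning, never a silent zero. The collinearity screen is greedy in
  ecological priority order with |r| > 0.85 as the default cutoff (the
  rule is published practice; the cutoff is this package's choice and is
  configurable).
* Percentage shares in composition tables round half-up to one decimal,
  matching how such tables are printed; base R's round-half-even would
  disagree on exact .05 boundaries.
* Degenerate cases error loudly rather than guessing: one-class training
  data, absent evaluation classes, constant surfaces in Moran's I,
  zero-variance columns under PCA scaling, empty crop windows, pseudo-
  absence shortfalls (the error names the shortfall).
* All randomness flows from one root seed through named substreams (kept
  below 2³¹), so every pipeline product — fold assignments, pseudo-
  absences, permutations, scenarios — is bit-reproducible.

## Problem sizes

The shipped tests exercise full pipelines on grids from 20 x 20 to
100 x 100 cells with 4–20 species; the default recovery scenario
(20 species x 3 algorithms x 20 folds x 10 replicates) is the largest
routine computation and runs in a few minutes on a single core. Gradient
and Moran computations accept a seeded cell subsample for larger grids.

## Known limitations

* Presence-only evaluation assumes absences at observed sites; community
  specificity and prediction success inherit that assumption.
* The ensemble is a weighted average; no per-cell algorithm selection or
  meta-learner stacking is attempted, and probability-sum richness
  (pSSDM) is out of scope by design.
* MaxEnt and MARS adapters are not shipped; the adapter contract accepts
  external implementations.
* No CRS reprojection: all layers must already share an affine grid
  alignment.
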