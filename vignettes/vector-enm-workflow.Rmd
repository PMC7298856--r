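---
title: "Modelling climatic suitability for the cattle tick: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climatic suitability for the cattle tick: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorenm)
```

`vectorenm` implements a complete ecological niche modelling (ENM)
workflow for mapping present and future climatic suitability of an
arthropod disease vector — the motivating system is the cattle tick
*Rhipicephalus (Boophilus) microplus* — and for translating projected
suitability change into exposure tables over livestock-abundance
categories and zoogeographic regions. This vignette describes the model,
the statistical procedures, the tunable parameters, and the design
decisions taken where more than one defensible choice existed.

## The suitability model

The core estimator is a Maxent-class presence-background model. Let
$f(x)$ be a vector of features derived from the environmental variables
at a grid cell $x$, and let the background be the set of cells in the
accessible area $M$. The model is the Gibbs distribution

$$P_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{\sum_{x' \in M} e^{\lambda \cdot f(x')}},$$

whose weights $\lambda$ maximize the L1-penalized log-likelihood of the
presence records,

$$\sum_{i=1}^{m} \log P_\lambda(x_i) \;-\; \sum_j \beta_j |\lambda_j|.$$

Feature classes follow the Maxent convention: linear (l), quadratic (q),
pairwise product (p), threshold (t) and hinge (h) transforms of the raw
variables, each min–max scaled to $[0,1]$ on the training background.
Threshold and hinge knots sit at evenly spaced quantiles of each
variable's background distribution (10 knots per variable by default),
so every knot lies inside the training range. Per-feature penalties are
the Maxent defaults: an interpolated, presence-sample-size-dependent
base penalty per class (l/q/p share one schedule; threshold has its own;
hinge is fixed at 0.5), multiplied by the feature's presence-sample
standard deviation over $\sqrt{m}$ and by the user's regularization
multiplier (RM). Only RM is exposed as a tuning grid — the study grid is
$\{0.1, 0.3, 0.5, 0.7, 1, 2, 3, 5, 7, 10\}$.

**Solver.** The weights are obtained by monotone FISTA: an accelerated
proximal-gradient scheme (gradient step on the smooth negative
log-likelihood, soft-thresholding for the L1 term, backtracking line
search) that accepts an accelerated candidate only when it does not
increase the penalized objective. The objective trace is therefore
monotone by construction, which the test suite asserts. Convergence is
declared when the objective decreases by less than `tol`
($10^{-7}$ relative) in an iteration; non-convergence within `max_iter`
(1000) yields a warning, never a silent success. This is a different
algorithm from the sequential-update solver in the Maxent reference
implementation; both optimize the same convex objective, but
bit-compatibility with that program is a non-goal.

**Output scales.** The *raw* output is $P_\lambda$ itself, normalized so
it sums to one over the training background (asserted to $10^{-6}$); it
is the scale on which the likelihood and AICc are computed. Maps use the
*cloglog* transform $1 - \exp(-e^{H} \cdot \mathrm{raw}(x))$, with $H$
the entropy of the fitted background distribution, which lies in
$[0,1]$ and is interpretable as suitability. During transfer to new
conditions, variables are clamped to the training range (the usual
transfer convention); extrapolation risk is reported separately by the
MOP analysis rather than hidden by clamping.

## Occurrence handling

Occurrences are point records in decimal degrees. All distances are
great-circle (haversine, sphere radius 6371.0088 km); degree offsets are
never converted to kilometres with a fixed factor. The preparation
stages are:

* **Spatial thinning** to a minimum separation (default 22 km, matching
  the ~0.2° working grid) to reduce the effect of sampling
  autocorrelation. The retained set must satisfy the pairwise-distance
  certificate exactly; subject to that, the algorithm keeps as many
  records as possible using a randomized greedy (repeatedly delete one
  member of a violating pair, preferring the record with more
  neighbours within the radius, across 100 seeded restarts, keeping the
  largest solution). On small instances the result matches the
  exhaustive maximum-independent-set optimum, which the tests verify.
  Thinning precedes the calibration/evaluation split by default — the
  order is an explicit choice; the reverse order is possible by calling
  the two functions in the other order.
* **Calibration/evaluation split**: a seeded random 50/50 partition
  (round half up for odd counts).
* **Accessible area (M)**: the union of 200-km haversine disks around
  the occurrences, rasterized by cell-center membership. M is both the
  calibration extent and the background for model fitting; if it holds
  more than `bg_max` (10,000) cells, a seeded uniform sample of 10,000
  is used, following common Maxent practice.

## Variable screening and candidate grid

Collinearity is reduced by greedy Pearson filtering over the masked
calibration cells: while any pair has $|r| \ge 0.80$, drop — from the
worst pair — the layer with the larger mean absolute correlation to all
remaining layers (ties break by name order, making the filter
deterministic). Candidate variable sets are all subsets of the retained
layers of size at least 2: seven retained variables give
$2^7 - 7 - 1 = 120$ sets. The candidate grid is the product of variable
sets, feature-class subsets (all 31 non-empty subsets of {l,q,p,t,h}
are available; runs configure a subset) and the RM grid.

Future layers arriving at coarser resolution are harmonized by additive
delta downscaling: the coarse future-minus-baseline anomaly is
bilinearly interpolated to the fine cell centers and added to the fine
baseline. The anomaly is additive for every variable, including relative
humidity, whose output can be clipped to [0, 100] %. The operation is
exactly the identity at zero anomaly and linear in the anomaly.

## Model selection

Candidates are screened in three stages:

1. **Significance** — partial ROC. The ROC curve is traced over the
   prediction raster's value distribution (x = fraction of cells
   predicted suitable, y = sensitivity of the evaluation points), and
   the partial AUC over the region with sensitivity $\ge 1 - E$
   (default $E = 0.05$) is compared with the area under the diagonal on
   the same x-range. Bootstrap iterations (500) resample half the
   evaluation points with replacement; the p-value is the fraction of
   iterations with AUC ratio $\le 1$. One deliberate refinement: the
   integration window is fixed from the *full* evaluation data before
   resampling. Re-selecting the window inside each iteration from the
   resampled (noisier) sensitivity curve conditions the window on
   upward noise and inflates the AUC ratio under the null — in our null
   simulations that variant ran at a ~19% type-I error at a nominal 5%,
   while the fixed window runs at ~6%. The package's null-calibration
   test (1000 simulated datasets) asserts the 0.05 ± 0.02 band.
2. **Performance** — omission. Predictions are thresholded at the
   E-percentile of the calibration suitabilities (the
   $(\lfloor E n \rfloor + 1)$-th smallest value, the largest threshold
   guaranteeing calibration omission $\le E$), and the omission rate of
   the evaluation points must not exceed $E$. If no significant
   candidate passes, selection falls back to minimum omission and the
   report is marked *relaxed* rather than failing.
3. **Complexity** — AICc, computed from the raw-scale likelihood at the
   calibration points with $k$ = number of nonzero feature weights
   ($|\lambda_j| > 10^{-8}$) and $n$ = calibration sample size;
   undefined (reported $+\infty$, flagged) when $k \ge n - 1$. Ties
   break by smaller $k$, then fewer variables, then id.

## Transfer, uncertainty and change classes

The selected parameterization is refit on 10 bootstrap resamples of the
calibration occurrences, and every projection (present plus each GCM ×
RCP × period stack) is the cell-wise median across replicates.
Projections are binarized at the present-day E-percentile threshold —
the same fixed threshold for all scenarios, because the change analysis
compares binary maps across time. Binarization uses calibration (not
evaluation) suitabilities, matching acceptable-omission thresholding
practice; this is configurable in the sense that any value vector can
be supplied.

Extrapolation risk is quantified by MOP (mobility-oriented parity): for
each projection cell, the mean standardized Euclidean distance
(per-variable scaling by the calibration range) to the nearest 10% of
calibration cells (capped at a seeded sample of 5000), rescaled to a
similarity in $[0,1]$; cells with any variable outside the calibration
min–max are flagged as strict extrapolation. Similarity is invariant
under affine rescaling of any single variable, which the tests check,
and the implementation matches a brute-force all-pairs oracle on small
grids to $10^{-9}$.

Ensemble uncertainty is summarized by per-cell agreement counts across
the GCM ensemble, with suitable/unsuitable decided at
$\ge \lceil 0.6\,G \rceil$ members (12 of 20). Present binary state and
future agreement combine into five change classes — stable-suitable
(strong agreement), suitable-weakening, strong gain, weak gain,
unsuitable — which partition the valid cells.

## Exposure tables

Change maps are overlaid with a cattle-abundance raster binned into the
categories {0–1, 1–5, 5–10, 10–20, 20–50, 50–100, >100} head per
10 km² (half-open intervals, final category $[100, \infty)$) and a
region raster. The percent modification of a (scenario, region,
category) stratum is defined as

$$100 \times \frac{\#\ \text{gain cells}}{\#\ \text{present-suitable cells}},$$

counting strong-agreement gains by default (all gains optionally). This
denominator is an interpretation — the source tables never state the
algebra — chosen because it is the only simple definition consistent
with published values exceeding 100%. The "both" scenario row is the
union of the individual scenarios' gain cells, which explains why it can
exceed each scenario separately; strata with no present-suitable cells
are reported as undefined, not zero. Cells above 10% are flagged.
Plain cell counts are used rather than cos(latitude) area weights; at
the 0.2° working resolution and tropical-to-temperate extents involved
the difference is small, and counts match the count-based reading of
the source tables.

## The synthetic study system

Real inputs (global bioclimatic layers, GCM ensembles, FAO livestock
rasters, curated occurrence databases) are large, licensed or
network-bound, so the package ships a generator that emulates their
statistical structure and makes every downstream stage testable
offline:

* **Environmental layers**: Gaussian random fields — white noise mixed
  through the matrix square root of a target correlation matrix, then
  smoothed with a separable Gaussian kernel (width 0.75 cells by
  default), re-standardized, and scaled to climate-like units. Mixing
  before smoothing preserves the cross-layer correlation, and the
  defaults recover requested pairwise correlations within ±0.1 on grids
  of 50×50 and larger. Defaults: 7 layers (the number of candidate
  variables in the motivating study) with pairwise correlation 0.3 —
  correlated, but below the 0.80 filter, so screening keeps all layers
  and the 120-set enumeration is exercised.
* **Truth surface**: cloglog of a linear + quadratic combination of the
  first 5 standardized layers (unimodal niches: zero linear, −1
  quadratic coefficients, intercept 0.5). The generating process lies
  inside the fitted l+q feature family by design, so parameter recovery
  is a meaningful acceptance surface.
* **Occurrences**: cells drawn with probability proportional to truth
  suitability, records placed at cell centers (no sub-cell jitter), so
  raster lookups are unambiguous in tests.
* **Futures**: baseline + per-scenario additive trend (warming-like,
  scaled by layer spread; twice as strong under the high-emissions
  scenario, 1.5× stronger by the later period) + independent per-GCM
  offsets; 20 pseudo-GCMs × 2 RCPs × 2 periods by default.
* **Cattle and regions**: an exponentiated smoothed Gaussian field
  (right-skewed, like real livestock densities) and contiguous
  longitude-band regions standing in for zoogeographic realms.

What the generator does *not* emulate: climate physics, spatially
correlated GCM disagreement, sampling bias in occurrence data,
coastlines and realistic realm geometry. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration of the
workflow, not predictive skill on real data.

## Numerical choices and degenerate inputs

* Constant prediction surfaces make the partial ROC undefined; the
  package returns ratio 1, p 1 with a warning.
* Constant (zero-variance) layers are removed by the Pearson filter
  with a warning before correlations are computed.
* Zero raw likelihood at any calibration point gives AICc $+\infty$
  with a flag; candidates are recorded as failed rather than dropped.
* All stochastic steps (thinning restarts, splits, background samples,
  bootstrap, partial ROC, MOP subsample, every generator) take explicit
  seeds; a single pipeline seed is expanded into per-stage seeds by a
  fixed scheme, so stages can be rerun in isolation and two runs of one
  config produce byte-identical outputs (checksummed in the run
  manifest).
* Problem sizes in tests and in the bundled demo configuration (60×60
  to 100×100 grids, 5–20 pseudo-GCMs, 5-set candidate grids, 300
  presences) were chosen so the full suite and the demo each complete
  in a few minutes on a single CPU while leaving the statistical checks
  (1000-replicate null calibration, 20-replicate recovery) adequately
  powered.

## Known limitations

* Raster I/O is plain-text ESRI ASCII grids; there is no GeoTIFF
  reader/writer and no reprojection — all inputs must share one
  geographic grid.
* The percent-modification definition and the "both = union" rule are
  documented interpretations of the source tables, not stated algebra.
* The Maxent variable-contribution heuristic tied to the reference
  implementation's sequential solver has no exact analogue under this
  package's solver and is not provided.
* Agreement counting treats ensemble members symmetrically; there is no
  GCM weighting.
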