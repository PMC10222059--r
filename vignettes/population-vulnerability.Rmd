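---
title: "Population-level climate-change vulnerability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level climate-change vulnerability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popvuln)
```

`popvuln` asks a population-biology question with species-distribution-model
machinery: when a climate projection says some populations of a narrow-range
plant will lose habitat suitability faster than others, do the censuses of
those populations already look different? The package implements the full
chain — predictor filtering, ensemble habitat-suitability modelling, a
standardized per-cell Climate Change Vulnerability Index (CCVI), stem-length
census summaries, and the association models linking the two — together with
a synthetic-landscape generator that makes the whole chain testable without
any geospatial downloads.

## The suitability ensemble

Occurrences are collapsed to one *valid occurrence* per grid cell (half-open
cell convention: a point on a shared edge belongs to the larger-coordinate
cell). Because only presences are observed, each model is fitted against
random *pseudo-absences*: cells drawn uniformly without replacement from the
non-presence domain. The full protocol crosses pseudo-absence draws with
stratified 70/30 calibration/test splits and with the chosen algorithms —
by default 5 pseudo-absence scenarios x 15 repetitions — and evaluates every
member by the True Skill Statistic

$$\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$$

at the member's own TSS-maximizing threshold on its test split (candidate
thresholds are midpoints of consecutive sorted unique scores; ties take the
lowest). Members with test TSS above 0.8 enter the ensemble with weights
proportional to their TSS; the ensemble score is the weighted mean of member
scores, reported on a 0–1000 integer suitability scale. The ensemble's own
binarization threshold — the "minimum suitable habitat" — is its
TSS-maximizing cut over all labelled cells.

Three learners are built in. The plain logistic regression (`"glm"`,
intercept + linear terms) is the reference learner with closed-form
behaviour, but a monotone linear learner cannot represent the *upper* edge of
a unimodal niche, so projections under a directional climate shift can only
increase; it is kept for contract and oracle purposes. The default learner is
`"glm_quadratic"` (linear plus squared terms), the customary GLM feature set
for unimodal climatic responses. `"maxent"` is an L1-regularized logistic
model on the same expanded features (the penalized-GLM formulation of
Maxent), with the penalty chosen by BIC along the regularization path —
the stable choice when presences are few. Any other algorithm attaches
through the learner contract `fit(X, y) -> function(X) -> [0, 1]`; a
randomForest probability adapter is included. Predictions are clipped to
`[1e-6, 1 - 1e-6]` so that perfect separation (flagged with a warning)
cannot produce infinite logits downstream.

Before fitting, the predictor stack is reduced to a low-collinearity subset:
while any pair of layers has |Pearson r| > 0.7, the member of the worst pair
with the larger mean |r| to all other layers is dropped (ties drop the layer
later in input order); then layers with variance inflation factor
VIF = 1/(1 − R²) of at least 10 are dropped highest-first. Both phases are
deterministic, and the kept set always satisfies both constraints. Exact
collinearity reports an `Inf` sentinel rather than an error.

## The vulnerability index

For one future scenario, let $s$ be the future ensemble suitability at the
cells of the *present* binary distribution (the footprint), $c$ a reference
suitability interpreted as the minimum needed for persistence, and $\sigma$
the sample standard deviation (n − 1) of the footprint values. Then

$$\mathrm{CCVI} = -\,\frac{s - c}{\sigma}.$$

A cell whose projected future suitability sits exactly at the survival
minimum scores 0; cells still suitable score negative; positive values mean
increasingly unsuitable futures. Because the index is centred and
sd-scaled, it is invariant under any consistent positive affine rescaling of
the suitability scale, which is what makes values comparable across species
and models.

Two centring modes are exposed because the choice is genuinely open: the
default centres on the ensemble's binarization threshold (the minimum
suitable habitat), matching the persistence interpretation; `center = "mean"`
centres on the footprint mean, in which case footprint CCVI has mean 0 and
sd 1 exactly. Per-plant values are read from the containing cell without
interpolation; plants in cells outside the footprint get `NA` with a
warning. Scenario averaging is a plain arithmetic mean per plant, and since
extraction is pointwise, averaging after extraction equals extracting from
an averaged surface. Population summaries report mean ± sample sd; a
single-plant population reports `NA` sd.

Two numerical caveats are deliberate. A footprint whose future suitability
is constant has no defined index (σ = 0) and errors; the pipeline treats
such a scenario as carrying no *relative* vulnerability information and
drops it from the averages with a message. And the index is antitone in
suitability *for a fixed scaling*: raising one cell's suitability while
re-estimating σ from the perturbed data can, in small footprints, raise that
cell's index through the shrinking denominator — so surfaces always report
the σ they used.

## Census summaries

Plants with stems of at most 30 cm are classified young, longer ones adult —
the threshold below which flowering is rare in the motivating system. Age is
proxied linearly from the species' stable leaf economy
(`age = stem_cm × leaves_per_cm / leaves_per_year`, defaults 0.6 and 3).
Per population the package reports counts, mean ± sd stem length,
Fisher–Pearson skewness (moment form `g1` by default; the adjusted `b1`
estimator is selectable because published tables rarely say which was used),
occupancy area, mean ± sd inter-plant distance, and densities per hectare.

The occupancy polygon is the convex hull (monotone chain + shoelace) by
default, or an alpha-shape — the union of Delaunay triangles (Bowyer–Watson)
with circumradius ≤ alpha — which follows concavities; `alpha = Inf`
recovers the hull, and `alpha = "auto"` in the summariser uses twice the
mean nearest-neighbour distance. "Mean distance between plants" is read as
the mean over all n(n−1)/2 pairwise distances (nearest-neighbour mean
offered as an option; the published wording is ambiguous). Degenerate
configurations (< 3 distinct non-collinear points) give area 0 with a flag,
and densities become `NA` sentinels, never infinities. Coordinates are
planar projected metres throughout; no geodesy.

## Association models

Population-level relations use ordinary least squares (overall F with
(1, n−2) df — identical to the squared slope t — R², Shapiro–Wilk residual
check, 95% slope CI) for continuous parameters, and a logit-link binomial
GLM on aggregated (young, adult) counts for proportions, reporting the Wald
Z of the slope. Count weighting is the default: it is equivalent to
weighting proportions by population size, which is what gives census-scale
Z statistics; an unweighted per-population mode exists but is non-default.

The GLM's fit measure deserves a note. On aggregated counts the deviance
ratio $1 - D_{model}/D_{null}$ and the strict McFadden ratio
$1 - \ell_{model}/\ell_{null}$ differ (they coincide only for ungrouped
data, where the saturated log-likelihood is 0). The deviance form is the
default (`r2_form = "deviance"`), reported as "McFadden (deviance form)";
the strict likelihood form is available.

Individual-level relations (stem length of fruiting plants vs per-plant
CCVI) use MM-type robust regression via `MASS::rlm(method = "MM")`:
high-breakdown S-estimate initialization, M-refinement with the Tukey
bisquare at 95% Gaussian efficiency. The robust slope test is reported as
F = t² with (1, n−2) df — a robust Wald test; how the published "F" for this
model family was derived is unstated, so its printed values are not a
target. The robust R² weights squared residuals and total variation by the
final IRLS weights. Slope comparisons between scenarios use 95%
confidence-interval overlap with a closed-interval convention (touching
endpoints overlap).

## The synthetic study system

The generator exists so that every stage — including the index — can be
validated against planted ground truth. Its defaults define one fixed study
system; they emulate the observable regime of a real small-endemic analysis,
and several were calibrated during design to keep that regime faithful:

* **Landscape.** Four predictor layers as smoothed Gaussian random fields
  (white-noise convolution with an isotropic Gaussian kernel), standardized
  to mean 0, sd 1 over cells; 96 × 96 cells of 1 km with autocorrelation
  range 4 cells. The extent-to-correlation-length ratio (~24 per side)
  matters: on smaller, smoother landscapes some realizations contain no
  cells beyond the occupied climatic range, the fitted niche then has no
  upper limb, and projected suitability loss can invert. Layers are
  abstract standardized predictors, not semantic bioclim variables.
* **Niche.** Gaussian, limited chiefly by one axis: optimum +0.8 spatial sd
  with width 0.6 on the first predictor; optimum 0 with width 1.5 on the
  others. A narrow optimum displaced on *every* axis would leave essentially
  no suitable cells, scattering occurrences diffusely in climate space; a
  single limiting gradient is both the realistic reading of a narrow-range
  endemic and the regime in which niche estimation from ~14 occurrences is
  stable.
* **Populations and coupling.** 13 populations with census sizes
  (11, 209, 109, 4, 77, 298, 22, 283, 181, 89, 251, 33, 48) — 1615 plants.
  Planted vulnerability `v` runs 0.2–0.8; population centres are drawn from
  the top suitability decile at first-axis targets increasing with `v`
  (matching the target on the coupling axis and the niche centre on the
  others), so higher-`v` populations sit closer to the warm niche edge and
  lose more suitability under the shift. The coupling to the index is thus
  geographic, not a label join.
* **Demography.** Stem lengths are gamma (positive, right-skewed, like the
  published distributions): mean `125 − 100 v` cm and young fraction
  `plogis(−2.2 + 3 v)`, with shape/scale solved from those two targets.
  Adults fruit with probability 0.28 and flower with 0.2; young plants
  flower with probability 0.02, below the ~5% field rarity. The planted
  contrast (≈60 cm in mean stem, young fraction ≈0.17→0.55 across
  populations) is of the same order as the published between-population
  contrasts.
* **Futures.** 5 GCM-like variants × 2 pathways. Shifts are +0.3 (low
  emission) and +0.55 (high emission) spatial sd on the limiting axis only,
  each GCM carrying a multiplicative N(1, 0.25²) factor, plus cellwise
  noise (sd 0.05). Shifts are deliberately a *fraction* of the landscape's
  spatial spread: mid-century change on a ~100 km mountain domain moves a
  site by less than the whole regional climate range, and inter-GCM spread
  of this order is typical of regional CMIP6 projections. Shifting the
  secondary axes adds population-specific loss unrelated to the planted
  gradient, so the default leaves them unshifted.
* **Pseudo-absences.** 1000 per scenario (field practice). The smaller
  `max(100, 10 × presences)` heuristic leaves so few background points
  beyond the occupied climatic range that the upper niche edge is
  unconstrained.

What the generator does *not* emulate: real bioclim covariance structure,
dispersal limitation and microsite effects, observation error in the census,
spatial autocorrelation of the demographic residuals, and real CMIP6
spatial anomaly patterns (futures are uniform shifts plus noise). Passing
tests therefore show that the pipeline recovers structure *when the
generating assumptions hold*, not that any field dataset satisfies them.

The headline validation (the package's acceptance suite runs it) repeats
the full pipeline across 50 seeds and checks that the planted signs —
negative slope of mean stem length on mean CCVI, positive slope of the
young-plant proportion — are recovered with p < 0.05 in at least 80% of
replicates. The problem sizes used there (96 × 96 landscape, 1615 plants,
75-member ensembles, 10 scenarios, 50 replicates) are the package's chosen
standard conditions and complete in a few minutes.

## Worked example

```{r example, eval = FALSE}
res <- run_vulnerability_pipeline(seed = 1)
res$summaries          # per-population census + CCVI table
res$associations       # the fitted model suite
autoplot(res$present_map)
autoplot(res$surfaces[[1]])
plot_size_structure(res$census)
```

Published-table checks need no simulation at all:

```{r repro, eval = FALSE}
reproduce_paper()
```

## Known limitations

* Rasters are in-memory matrices with planar geometry; the on-disk format
  is the plain-text ESRI ASCII grid. There is no GeoTIFF writer and no CRS
  handling beyond a label.
* The Bowyer–Watson triangulation is O(n²) in plain R — fine for censuses
  of hundreds of plants, slow for many thousands of points.
* The ensemble pools test data for its own threshold; with tiny presence
  samples the threshold is optimistic relative to spatially blocked
  validation, which is out of scope.
* Single-cell populations make the population CCVI equal the cell CCVI;
  within-population sd then reflects only scenario noise, not space.
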