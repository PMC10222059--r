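# popvuln

Population-level climate-change vulnerability analysis for narrow-range
plants.

## The problem

Species distribution models (SDMs) routinely say *where* a species will lose
climatically suitable habitat, but rarely say anything about the populations
standing in those places today. For a censused endemic plant the interesting
question is demographic: do populations that an ensemble SDM projects to
lose suitability fastest already show shorter-lived adults and a larger
share of young plants? `popvuln` implements the full analysis chain needed
to ask that question, for ecologists working with a georeferenced census, a
stack of climate predictor rasters, and a set of future climate scenarios:

1. **Predictor selection** — reduce a predictor stack to a low-collinearity
   subset (pairwise Pearson |r| ≤ 0.7, VIF < 10).
2. **Ensemble SDM** — presences + random pseudo-absence scenarios,
   stratified 70/30 calibration/test splits, repeated fits of pluggable
   learners (logistic GLM, quadratic GLM, maxent-style penalized GLM,
   random forest), member evaluation by the True Skill Statistic
   (TSS = sensitivity + specificity − 1) at each member's optimal threshold,
   and a TSS-weighted ensemble on a 0–1000 suitability scale with its own
   minimum-suitable-habitat threshold.
3. **Climate Change Vulnerability Index** — per cell of the present
   distribution footprint, with future suitability *s*, survival-minimum
   centre *c* (default: the ensemble threshold) and footprint standard
   deviation σ:

   CCVI = −(s − c) / σ

   0 at the survival limit, negative where the future stays suitable,
   increasingly positive with vulnerability; standardized, hence comparable
   across scenarios and species. Extracted per plant, averaged over
   scenarios, summarized per population.
4. **Demography** — stem-length censuses summarized per population: life
   stages (young ≤ 30 cm), age proxy (stem × 0.6 leaves/cm ÷ 3 leaves/yr),
   skewness, convex-hull or alpha-shape occupancy area, inter-plant
   distances, densities.
5. **Association** — linear models for continuous population parameters,
   count-weighted binomial GLMs (with McFadden-style pseudo-R²) for
   proportions, MM-type robust regression for per-plant relations, and
   slope comparisons via confidence-interval overlap.

A seeded synthetic-landscape generator (autocorrelated climate fields, a
Gaussian niche, clustered occurrences, censuses with a *planted* coupling
between vulnerability and demography) makes the entire chain testable
end-to-end with known ground truth. See the methods vignette
(`vignettes/population-vulnerability.Rmd`) for the models, assumptions and
design decisions.

## Worked example

```r
library(popvuln)
res <- run_vulnerability_pipeline(seed = 1)
print(res)
```

```
<vulnerability_analysis> seed 1: 1615 plants in 13 populations
  ensemble: 67 members, TSS 1.000, threshold 843/1000
  association models:
   Mean stem length (cm)              CCVI 2055              F =    7.303  p = 0.0206
   Proportion of young plants (%)     CCVI 2055              Z =    7.436  p = 1.04e-13
   Mean stem length (cm)              CCVI 2055 SSP5-RCP8.5  F =    8.986  p = 0.0121
   Proportion of young plants (%)     CCVI 2055 SSP5-RCP8.5  Z =    7.688  p = 1.49e-14
   Stem length (cm) (Fruiting plants) CCVI 2055              F =    0.735  p = 0.392
   Stem length (cm) (Fruiting plants) CCVI 2055 SSP5-RCP8.5  F =    0.273  p = 0.602
```

The synthetic study system plants a negative effect of vulnerability on
mean stem length and a positive one on the young-plant fraction; the fitted
models above recover both directions with p < 0.05 at the population level
(the per-plant fruiting-stem coupling is not planted, and correctly reads
as null). Per-population detail and the planted truth are in
`res$summaries` and `res$populations`:

```r
dplyr::select(res$summaries, population, n_plants, mean_stem_cm, n_young, n_adult, mean_ccvi)
#>   population n_plants mean_stem_cm n_young n_adult mean_ccvi
#> 1 P01              11         94.1       1      10     -1.44
#> 2 P02             209         93.6      50     159     -1.51
#> 3 P03             109         90.1      27      82     -1.41
#> 4 P04               4         54.3       2       2     -1.19
#> ...
```

`autoplot()` works on suitability maps, vulnerability surfaces and fitted
models; `plot_size_structure()` draws the per-population scaled kernel
densities of stem length.

The package also ships the published 13-population parameter table as a
plain-text fixture and can re-derive the published summary statistics from
it deterministically:

```r
reproduce_paper()
#> # A tibble: 16 × 5
#>   check                       value target tolerance pass
#>   <chr>                       <dbl>  <dbl>     <dbl> <lgl>
#> 1 total plants                1615    1615       0   TRUE
#> 2 plants per population (min)    4       4       0   TRUE
#> 3 plants per population (max)  298     298       0   TRUE
#> 4 mean plant density (n/ha)    792.    792       0.5 TRUE
#> ...   (16 checks, all passing)
```

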