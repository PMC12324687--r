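# perfscape

Spatial statistics for population mapping of cerebral blood perfusion.

Arterial-spin-labeling MRI yields one perfusion map (ml/100g/min) per
participant. Questions about how perfusion is organized across the cortex —
what the shared spatial pattern is, how it changes with age and sex, which
molecular annotations track it, which physiological biomarkers co-vary with
it, and how inter-subject covariance partitions the cortex into
vascular-territory-like blocks — all reduce to a small set of statistical
machines. `perfscape` implements that machinery as composable R functions,
and ships a synthetic spherical cohort generator with planted ground truth so
every stage can be validated end to end by recovery and calibration tests.

## What is implemented

- **Perfusion score maps** — subjects are z-scored (`standardize_subjects()`)
  and the first right singular vector of the stacked matrix is the dominant
  shared spatial pattern (`pca_score_map()`), with per-subject loadings and
  variance-explained fractions.
- **Spatial-autocorrelation-preserving nulls** — brain maps are smooth, so
  naive permutation tests are anticonservative. Three null families over a
  spherical parcel geometry: centroid rotations with nearest-parcel
  reassignment (`spin_assignments()`), bijective "unique" reassignment
  (`vasa_assignments()`), and variogram-matched surrogates
  (`variogram_surrogates()`). All p-values use the inclusive add-one
  convention `p = (1 + #extreme) / (1 + N)`, so the floor at `N = 1000` is
  `1/1001 = 9.99e-4`.
- **Per-parcel GLMs** — `value = b0 + b1 age + b2 sex (+ interactions)` at
  every location with Bonferroni masks (`glm_effect_maps()`), covariate
  residualization (`residualize_covariates()`), and group contrasts of
  effect maps against the spin null (`network_contrast()`).
- **Ensemble-null category enrichment** — the category score is the mean
  Fisher-z correlation of member annotation maps with a target map; the null
  replaces the *target* with autocorrelation-matched surrogates
  (`run_gcea()`, `differential_stability()`).
- **Behavioral PLS** — SVD of the z-scored cross-block matrix `X'Y = USV'`;
  brain scores `XU`, biomarker scores `YV`, covariance explained
  `s_k^2 / sum(s^2)`; inference by row permutation, bootstrap ratios, and
  80/20 train/test cross-validation (`pls_fit()`, `pls_permutation()`,
  `pls_bootstrap()`, `pls_crossval()`), plus exact dominance analysis
  (`dominance_analysis()`).
- **Normative trajectories** — generalized-gamma location-scale-shape model
  `Y ~ GG(mu(age), sigma(age), nu)` with two-term fractional-polynomial
  predictors chosen from powers `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` by
  exhaustive GAIC search (`fit_gg_fp()`, `centile_curves()`; distribution
  functions `dgg/pgg/qgg/rgg`).
- **Covariance gradients** — double z-scoring, inter-subject covariance,
  diffusion-map embedding (`perfusion_covariance()`,
  `diffusion_gradients()`, `annotate_gradients()`).
- **Synthetic cohorts** — `simulate_cohort()` plants a shared smooth map, a
  sex offset, region-dependent age slopes, territory block covariance and a
  low-rank biomarker coupling, all on a log-link mean model with generalized
  gamma noise; `simulate_annotations()` plants an enriched category.
  `run_pipeline()` chains everything.

Results come back as tibbles or as objects with `tidy()` / `glance()` /
`autoplot()` methods, so they drop straight into dplyr/ggplot2 workflows.

## Worked example

```r
library(perfscape)

geom   <- sphere_geometry(400)                      # spherical parcel geometry
cohort <- simulate_cohort(cohort_config(seed = 1), geom)
cohort
#> <synthetic_cohort> 200 subjects x 400 parcels, ages 8.2-79.8, 28 biomarkers

scores <- pca_score_map(standardize_subjects(cohort$subject_matrix))
scores
#> <score_map_result> PC1 explains 73.45% of variance (PC2: 17.97%)
cor(scores$score_map, cohort$truth$shared_map)
#> [1] 0.986

ens     <- spin_assignments(geom, n_null = 1000, seed = 2)
glm_tab <- glm_effect_maps(log(cohort$subject_matrix), cohort$covariates)
network_contrast(coefficient_map(glm_tab, "age"),
                 cohort$truth$network == "transmodal", ens)
#> # A tibble: 1 x 5
#>      delta statistic p_parametric   p_spin n_null
#>      <dbl>     <dbl>        <dbl>    <dbl>  <int>
#> 1 -0.00566     -49.3    1.40e-154 0.000999   1000
```

Reading the output: PC1 carries 73% of the variance and correlates 0.986
with the planted shared map, so the score map is the cohort's common
perfusion pattern, not noise. The age-slope contrast between the transmodal
and unimodal caps is negative (transmodal perfusion declines faster with
age, as planted), significant both parametrically and against 1000 spins —
and the spin p-value sits exactly at the `1/1001` floor of the inclusive
convention.

## Vignette

`vignettes/perfscape-methods.Rmd` documents the models, the synthetic study
conditions, every tunable default, and the numerical design choices.
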