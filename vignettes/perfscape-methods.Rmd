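---
title: "perfscape: models, study conditions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perfscape: models, study conditions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`perfscape` implements the statistical machinery used in population studies
of cerebral blood perfusion: score maps, spatial nulls, category enrichment,
behavioral PLS, generalized-gamma normative trajectories and covariance
gradients. This vignette is the package's account of those methods — what
each model assumes, what every tunable default is and why, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## The synthetic cohort: study conditions

Real lifespan perfusion cohorts are restricted-access; the package therefore
validates itself on a synthetic cohort whose statistical structure mirrors
what the analyses assume. `simulate_cohort()` draws, for subject $i$ and
parcel $v$ on a unit sphere,

$$ y_{iv} \sim \mathrm{GG}(\mu_{iv},\ \sigma,\ \nu), \qquad
   \mu_{iv} = \exp\big(m_0 + c\, m_v + s\,\mathbb{1}[\text{female}_i]
   + b_v (\text{age}_i - \bar a) + t_{i,\tau(v)}\big) $$

with $m$ a smooth random field (the shared perfusion pattern), $b$ a
region-dependent age-slope field, and $t$ per-subject territory factors.
The mean model is multiplicative (log link) so that no combination of
effects can yield negative perfusion, and the observation noise is the same
generalized-gamma family the trajectory module fits — positive and
right-skewed, as perfusion data are.

Defaults, chosen once as a realistic regime and then left alone:

| parameter | default | rationale |
|---|---|---|
| subjects, parcels | 200, 400 | desk-scale analog of a multi-hundred cohort on a ~400-parcel cortical atlas |
| ages | uniform 8–80 y | lifespan span; two disjoint ranges supported to mimic a development + aging two-cohort design |
| baseline | $\exp(m_0) = 50$ ml/100g/min | typical grey-matter perfusion |
| shared map scale $c$ | 0.3 (log scale) | ±30% regional variation around baseline, enough for PC1 to dominate |
| sex offset $s$ | 0.1 (log scale) | ~10% higher female perfusion |
| base slope | −0.005 /y (log), ×2 in a "transmodal" cap | ~0.5%/y decline, doubled in association-like cortex; smooth jitter sd 0.001 makes the slope field a field rather than two constants |
| territory factors | 2 longitude sectors, sd 0.25 | block covariance dominating the doubly-standardized correlation, as territory analyses assume |
| GG noise | $\sigma = 0.08$, $\nu = 1.5$ | ~8% measurement noise, mildly right-skewed |
| biomarkers | 28 measures, 10 coupled at $r = 0.8$ to the (negated) age latent | low-rank perfusion–biomarker coupling for PLS |
| field lengthscale | 0.4 rad | smooth enough that ~25 effective spatial degrees of freedom remain — the regime in which naive correlation tests break and spatial nulls are necessary |

The three partitions are deliberately different axes of the sphere:
hemispheres split on $x$, the unimodal/transmodal caps on $z$, and
territories on longitude sectors, so that recovery of one structure cannot
be an artifact of another.

What the generator does *not* emulate: voxel-level imaging, arterial signal
physics, vascular anatomy, site effects, non-uniform parcel sizes, or
covariate distributions beyond uniform age and balanced sex. Passing tests
therefore certify the statistical machinery, not robustness to acquisition
artifacts.

## Score maps and GLMs

Subjects are z-scored individually (sample sd, divisor $n-1$ — used
everywhere z-scoring appears in the package), which removes global offsets
such as mean sex differences. The score map is the first right singular
vector of the stacked matrix. Columns are *not* centered by default: the
shared mean pattern is exactly what the first component should capture, and
an uncentered SVD lets it. Textbook column-centered PCA is available via
`center_columns = TRUE`; with the default cohort the two differ mainly in
how much variance PC1 absorbs. The score map's sign is fixed so it
correlates non-negatively with the column mean map.

Per-parcel GLMs use `sex` coded male = 1, female = 0, two-sided t-based
p-values, and a Bonferroni mask at family-wise 0.05. The recovery tests run
the GLM on log perfusion, where the generator's slopes live; on the raw
scale an additive fit recovers the log-scale slopes only approximately
(small-effect regime), which is why the generator keeps effects modest.
`residualize_covariates()` projects out the full cubic age basis with sex
interactions via the QR decomposition (`qr.resid`), keeping residuals
orthogonal to the design to machine precision despite the badly scaled
`age^3` columns.

## Spatial nulls

Spin nulls rotate parcel centroids by Haar-uniform rotations (QR of a
Gaussian matrix with sign fix) and reassign each original parcel the value
of its nearest rotated parcel; rotated parcels inside an exclusion mask (the
medial-wall analog) never donate — the next closest parcel is used. With two
hemispheres, `mirror = TRUE` applies the x-reflected rotation to the right
hemisphere and matches within hemisphere. The Váša variant forces a
bijective matching, greedily by ascending distance with uniqueness enforced
and ties broken at the lowest index; an optimal-assignment mode
(Jonker–Volgenant) sits behind `method = "optimal"`. These rules are this
package's own documented conventions — external toolboxes do not specify
their tie-breaking — and the tests therefore verify *calibration* (false
positive rate within its Monte-Carlo band, p-value uniformity), not
bit-parity with any toolbox.

Variogram surrogates serve geometries without spherical centroids: permute
the map, smooth at each of 10 candidate scales (geometric grid from the
smallest positive distance to $\pi/2$), select the scale whose binned
variogram (25 equal-count bins) best matches the source under weights
$1/\gamma^2$ — weighting matches the short-range bins that carry the
autocorrelation, and makes a white-noise source select the smallest scale —
and rank-remap onto the original value multiset. Each surrogate takes the
best of 5 permutation restarts, judged by realized mean relative variogram
deviation. The restart step matters: an *unconditioned* draw from the same
smoothing family deviates from a given source realization's variogram by
~20% on average at lengthscale 0.4 (the realization's own long-range
structure is irreproducible), while best-of-5 conditioning brings surrogates
inside 10%.

All permutation p-values are inclusive: $p = (1 + \#\{\text{extreme}\}) /
(1 + N)$, never zero, with floor $1/(N+1)$. Map–map correlations default to
two-sided tests; enrichment scores to one-sided positive. $N = 1000$ is the
default ensemble size.

In the calibration test (200 independent smooth-field pairs, 1000 spins),
one spin ensemble is shared across the 200 pairs: the ensemble depends only
on the geometry, never on the maps, so the rejection-rate estimate is
unbiased and regenerating 200 ensembles would buy nothing but runtime.

## Category enrichment

The category score is the mean Fisher-z-transformed Pearson correlation of
member maps with the target, with $|r|$ clipped at $1 - 10^{-7}$ so a
perfect member stays finite. The null replaces the **target** with each
ensemble map — never the annotation maps — so inter-member correlation
structure is preserved under the null. Positive-sided inclusive p-values are
BH-FDR corrected. Both the raw score and a null-standardized z-score are
reported, since ranking conventions differ between toolboxes. Annotations
can be pre-filtered by differential stability (mean inter-donor correlation,
threshold 0.1) and categories by minimum size (default >30 members, the GO
convention; the synthetic battery lowers it to keep its small decoys).

One discreteness fact worth knowing: with $m$ categories, one true positive
and $N$ nulls, the smallest attainable FDR-adjusted p is $m/(N+1)$. At
$m = 51$, detection at $q = 0.05$ therefore needs $N \ge 1020$; the
enrichment battery runs $N = 2000$.

## Behavioral PLS and dominance analysis

Columns of both blocks are z-scored; $R = X'Y$ is decomposed $R = USV'$
with $U$ over locations and $V$ over measures, so brain scores are $XU$ and
biomarker scores $YV$. Covariance explained is $s_k^2/\sum s^2$ (invariant
to any overall scaling of $R$). Permutations shuffle rows of $X$ only
(shuffling $Y$ is equivalent in distribution and available); permuted
singular values are compared per ordered component. Bootstrap resamples are
sign-aligned to the original by the inner-product sign of the concatenated
singular vectors — adequate in the single-dominant-LV regime; multi-LV use
would need Procrustes alignment and is a documented limitation. A bootstrap
weight with zero resampling sd yields a signed-infinite ratio plus a
warning. Cross-validation refits column statistics on the training fraction
only, projects held-out subjects, and tests the mean out-of-sample score
correlation against splits of row-shuffled data.

Dominance analysis enumerates all $2^p$ predictor subsets exactly (refusing
$p > 20$) and averages each predictor's incremental $R^2$ within subset
size, then across sizes; contributions sum to the full-model $R^2$ by
construction, which the tests assert to $10^{-10}$.

## Generalized-gamma trajectories

The Stacy parameterization is used throughout: with
$\theta = 1/(\sigma^2\nu^2)$, $\theta (y/\mu)^\nu \sim \Gamma(\theta)$, so
$\nu = 1$ is a gamma law with mean $\mu$ and $\nu < 0$ follows by the
reciprocal transform. $\nu = 0$ (the lognormal limit) is not parameterized
and is rejected. Quantiles invert the gamma CDF directly (reflected for
$\nu < 0$).

Fractional-polynomial designs map power 0 to $\log x$ and a repeated power
$p$ to $(x^p, x^p \log x)$. Ages are divided by 10 (decades) for
conditioning, with an automatic positive shift recorded in the fit if any
age is non-positive. The search enumerates all 8 one-term and 36 two-term
(28 distinct + 8 repeated) power combinations for $\mu$ with $\sigma$
intercept-only, then repeats the enumeration for $\sigma$ holding the
winning $\mu$ powers — a two-stage scheme that bounds the fit count; a
joint search flag exists for small data. Whether the scale deserves its own
fractional polynomial is genuinely open; two-stage is the documented
default. Each candidate is fitted by BFGS maximum likelihood on
$(\beta_\mu, \beta_\sigma, \nu)$ with log links for $\mu$ and $\sigma$,
moment-based initialization from a log-scale least-squares fit, up to 3
restarts (jitter sd 0.2), relative tolerance $10^{-10}$, and guard rails
($|\nu| \in [10^{-3}, 20]$, bounded linear predictors) that return a large
objective rather than NaN. Winner by GAIC $= -2\ell + k\,\text{npar}$ with
$k = 2$ (AIC); $k$ is exposed. The shape $\nu$ is weakly identified at
moderate $n$ — median curves and centile coverage are accurate long before
$\hat\nu$ is — so recovery is asserted on curves and coverage, not on
$\hat\nu$.

## Covariance gradients

Subject maps are z-scored within subject, each location z-scored across
subjects, and the location × location correlation computed. Row z-scoring
has a structural consequence: with two balanced territories the two factors
become exactly anticorrelated (each row sums to zero), so *every*
between-territory correlation is negative. An affinity built by clipping
negatives to zero therefore disconnects into the two blocks — which is why
the default affinity is the diffusion-toolbox convention instead:
per-row sparsification (top `1 - sparsity` fraction kept), then the
normalized-angle kernel $1 - \arccos(\text{cosine similarity})/\pi$ of the
sparsified rows, which is strictly positive and keeps anticorrelated blocks
weakly connected. The literal clip recipe remains available as
`kernel = "clip"` and raises the documented disconnection error on such
inputs.

The operator is $\alpha$-normalized ($\alpha = 0.5$, Fokker–Planck
scaling), row-normalized to a Markov transition matrix, and
eigendecomposed via its symmetric conjugate. The constant eigenvector is
dropped; gradients are the next $k$ right eigenvectors scaled by their
eigenvalues, signs fixed so the largest-magnitude loading is positive.
Default row sparsity is 0.9 (toolbox convention). For the default
two-balanced-territory cohort the territory analyses use sparsity 0.5: with
balanced blocks, a row's informative entries are exactly its within-block
half, while keeping only the top 10% reduces each row to a random subsample
of that half and saturates the cosine kernel. This is a property of the
block geometry, decided from it.

## Problem sizes and runtime

The validation battery runs at the generator's native conditions — 400
parcels, cohorts of 200–500, ensembles of 1000 (2000 for enrichment), 1000
permutations/bootstraps/splits, 200-repeat calibration loops, trajectory
fits at $n$ = 800 and 2000 — sizes chosen so every Monte-Carlo band in the
tests is meaningfully tight on a single CPU.

## Known limitations

- Single-sphere geometry by default; two-hemisphere support covers mirrored
  spins but not inter-hemispheric distance asymmetries of real surfaces.
- Spin/Váša tie-breaking and the surrogate restart rule are this package's
  conventions; other implementations will differ at the bit level.
- Bootstrap sign alignment is per-component, not Procrustes.
- The additive GLM on raw perfusion is a small-effect approximation to the
  generator's multiplicative truth; use log perfusion when slopes matter.
- Dominance analysis is exact and exponential; 20 predictors is the hard
  ceiling.
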