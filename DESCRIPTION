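Package: perfscape
Title: Spatial Statistics for Lifespan Cerebral Perfusion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for population mapping of cerebral blood
    perfusion: principal-component perfusion score maps, spatial-
    autocorrelation-preserving permutation nulls (centroid spins, unique
    parcel reassignment, variogram-matched surrogates), ensemble-null gene
    category enrichment, behavioural partial least squares with permutation
    and bootstrap resampling, generalized-gamma fractional-polynomial
    normative trajectories, and diffusion-map gradients of inter-subject
    perfusion covariance. Includes a synthetic spherical cohort generator
    with planted ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
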