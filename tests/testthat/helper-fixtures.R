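# Small shared fixtures, built once per test run.

geom50 <- sphere_geometry(50)
geom100 <- sphere_geometry(100)
geom400 <- sphere_geometry(400)

# tiny deterministic cohort for structural tests
tiny_cohort <- simulate_cohort(
  cohort_config(n_subjects = 40, n_parcels = 50, seed = 99), geom50
)

build_design_for_test <- function(cov) {
  perfscape:::build_design(cov, c("age", "sex", "age:sex", "age^2",
                                  "sex:age^2", "age^3", "sex:age^3"))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
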