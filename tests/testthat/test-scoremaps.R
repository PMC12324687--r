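test_that("subject standardization matches hand values and is scale invariant", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))
  z <- standardize_subjects(m)
  expect_equal(z[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z[1, ], z[2, ], ignore_attr = TRUE)

  set.seed(1)
  r <- matrix(rnorm(500), 10, 50)
  zr <- standardize_subjects(r)
  expect_lt(max(abs(rowMeans(zr))), 1e-12)
  expect_equal(apply(zr, 1, sd), rep(1, 10), tolerance = 1e-12)

  expect_error(standardize_subjects(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})

test_that("PCA score map: rank-1 input, sign convention, variance fractions", {
  m <- standardize_subjects(rbind(c(1, 2, 3), c(2, 4, 6)))
  res <- pca_score_map(m, n_components = 2)
  expect_equal(res$variance_explained[1], 1)
  expect_gte(cor(res$score_map, colMeans(m)), 0)

  set.seed(2)
  big <- standardize_subjects(matrix(rexp(20 * 30), 20, 30))
  full <- pca_score_map(big, n_components = 20)
  expect_equal(sum(full$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(full$variance_explained) <= 1e-12))
  expect_gte(cor(full$score_map, colMeans(big)), 0)

  expect_error(pca_score_map(big, n_components = 25), "exceeds")
  expect_warning(pca_score_map(matrix(rexp(100), 5, 20)), "standardized")
})

test_that("PC1 of the standardized cohort recovers the planted shared map", {
  coh <- simulate_cohort(cohort_config(seed = 42), sphere_geometry(400))
  res <- pca_score_map(standardize_subjects(coh$subject_matrix))
  expect_gte(abs(cor(res$score_map, coh$truth$shared_map)), 0.95)
})

test_that("GLM effect maps equal the closed-form least-squares solution", {
  cov <- tibble::tibble(age = c(10, 20, 30, 40, 55, 70), sex = c(1, 0, 1, 0, 1, 0))
  # noiseless single-location model
  y <- matrix(3 + 2 * cov$age, ncol = 1)
  tab <- glm_effect_maps(y, cov, terms = "age")
  expect_equal(tab$estimate[tab$term == "(Intercept)"], 3, tolerance = 1e-10)
  expect_equal(tab$estimate[tab$term == "age"], 2, tolerance = 1e-10)

  # random multi-location case against (X'X)^-1 X'y and lm()
  set.seed(3)
  ym <- matrix(rnorm(6 * 4), 6, 4)
  tab2 <- glm_effect_maps(ym, cov, terms = c("age", "sex"))
  for (j in 1:4) {
    ref <- lm(ym[, j] ~ age + sex, data = cov)
    got <- tab2[tab2$location_index == j, ]
    expect_equal(got$estimate, unname(coef(ref)), tolerance = 1e-10)
    expect_equal(got$std_error, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-10)
    expect_equal(got$p_value,
                 unname(summary(ref)$coefficients[, 4]), tolerance = 1e-10)
  }

  expect_error(
    glm_effect_maps(ym, dplyr::mutate(cov, age = 1), terms = c("age", "sex")),
    "collinear"
  )
})

test_that("residualization annihilates design-spanned signal and is orthogonal", {
  set.seed(4)
  cov <- tibble::tibble(age = runif(30, 5, 80), sex = rep(c(0, 1), 15))
  x <- build_design_for_test(cov)
  b <- matrix(rnorm(8 * 5), 8, 5)
  y_exact <- x %*% b
  res <- residualize_covariates(y_exact, cov)
  expect_lt(max(abs(res)), 1e-8)

  y_noise <- y_exact + matrix(rnorm(150), 30, 5)
  res2 <- residualize_covariates(y_noise, cov)
  xn <- sweep(x, 2, sqrt(colSums(x^2)), "/") # per-unit-norm column orthogonality
  expect_lt(max(abs(crossprod(xn, res2))), 1e-8)

  # refitting the same design on residuals returns ~zero coefficients
  tab <- glm_effect_maps(res2, cov,
                         terms = c("age", "sex", "age:sex", "age^2",
                                   "sex:age^2", "age^3", "sex:age^3"))
  expect_lt(max(abs(tab$estimate)), 1e-8)
})

test_that("score map is stable under covariate residualization for small effects", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 100, n_parcels = 100, base_slope = -0.001,
                  sex_offset = 0.02, seed = 12),
    geom100
  )
  z <- standardize_subjects(coh$subject_matrix)
  raw <- pca_score_map(z)
  resd <- residualize_covariates(coh$subject_matrix, coh$covariates)
  # restore the location means so the shared pattern (not the covariate
  # effects) is what the comparison sees
  resd <- sweep(resd, 2, colMeans(coh$subject_matrix), "+")
  res <- pca_score_map(standardize_subjects(resd))
  expect_gte(abs(cor(raw$score_map, res$score_map)), 0.9)
})

test_that("strength map sums absolute off-diagonal weights", {
  w <- rbind(c(0, -0.5), c(-0.5, 0))
  expect_equal(strength_map(w), c(0.5, 0.5))
  expect_equal(strength_map(matrix(0, 3, 3)), rep(0, 3))

  set.seed(5)
  w5 <- matrix(rnorm(25), 5, 5)
  brute <- vapply(1:5, function(j) {
    s <- 0
    for (k in 1:5) if (k != j) s <- s + abs(w5[k, j])
    s
  }, numeric(1))
  expect_equal(strength_map(w5), brute)
  expect_error(strength_map(matrix(0, 2, 3)), "square")
})

test_that("network contrast: null case, forced extreme, and spin p-value", {
  labels <- rep(c(TRUE, FALSE), 25)
  same <- rep(1:5, 10)
  res0 <- network_contrast(same, labels)
  expect_equal(res0$delta, 0)
  expect_equal(res0$statistic, 0)

  ens <- spin_assignments(geom50, n_null = 99, seed = 1)
  map <- smooth_field(geom50, 0.4, seed = 2)
  grp <- geom50$coords[, 3] > 0
  map_shift <- map + 10 * grp
  res <- network_contrast(map_shift, grp, ens)
  expect_lt(res$p_parametric, 1e-10)
  expect_equal(res$p_spin, 1 / 100)

  expect_error(network_contrast(map, rep(TRUE, 50)), "non-empty")
})
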