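test_that("PLS covariance explained matches constructed singular values", {
  # orthogonal design: cor(x1,y1) = 1, cor(x2,y2) = 0.5 => singular values
  # in ratio 2:1 => covariance explained (0.8, 0.2)
  u1 <- c(1, -1, 1, -1); u2 <- c(1, 1, -1, -1); u3 <- c(1, -1, -1, 1)
  x <- cbind(u1, u2)
  y <- cbind(u1, (u2 + sqrt(3) * u3) / 2)
  m <- pls_fit(x, y)
  expect_equal(m$covariance_explained[1:2], c(0.8, 0.2), tolerance = 1e-12)

  # single-column Y: one latent variable carries everything
  m1 <- pls_fit(x, cbind(u1))
  expect_equal(m1$covariance_explained[1], 1)

  # stored brain scores reproduce their definition exactly
  expect_equal(m$brain_scores, m$x %*% m$u, tolerance = 1e-12)
  expect_equal(m$biomarker_scores, m$y %*% m$v, tolerance = 1e-12)

  # orthonormality of singular vector blocks
  expect_equal(crossprod(m$u), diag(2), tolerance = 1e-8)
  expect_equal(crossprod(m$v), diag(2), tolerance = 1e-8)

  expect_error(pls_fit(x, cbind(rep(1, 4))), "constant")
})

test_that("PLS is invariant to affine rescaling of input columns", {
  set.seed(11)
  x <- matrix(rnorm(200), 20, 10)
  y <- matrix(rnorm(80), 20, 4)
  m1 <- pls_fit(x, y)
  x2 <- sweep(sweep(x, 2, runif(10, 0.5, 3), "*"), 2, rnorm(10), "+")
  m2 <- pls_fit(x2, y)
  expect_equal(m1$singular_values, m2$singular_values, tolerance = 1e-10)
  expect_equal(abs(m1$u[, 1]), abs(m2$u[, 1]), tolerance = 1e-10)
})

test_that("first PLS component agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  x <- matrix(rnorm(600), 30, 20)
  y <- x %*% matrix(rnorm(80), 20, 4) + matrix(rnorm(120), 30, 4)
  m <- pls_fit(x, y)
  ref <- mixOmics::pls(x, y, ncomp = 1, mode = "canonical", scale = TRUE)
  expect_gt(abs(cor(m$u[, 1], ref$loadings$X[, 1])), 1 - 1e-8)
  expect_gt(abs(cor(m$v[, 1], ref$loadings$Y[, 1])), 1 - 1e-8)
})

test_that("permutation p-values follow the inclusive convention and detect coupling", {
  set.seed(13)
  n <- 60
  latent <- rnorm(n)
  x <- matrix(0.7 * latent + 0.3 * rnorm(n * 15), n, 15)
  y <- cbind(0.9 * latent + 0.3 * rnorm(n), matrix(rnorm(n * 3), n, 3))
  m <- pls_fit(x, y)
  perm <- pls_permutation(m, n_perm = 99, seed = 1)
  expect_equal(perm$p_value[1], 1 / 100)

  # single permutation below the observed value: p = 1/2 by convention
  p1 <- pls_permutation(m, n_perm = 1, seed = 2)
  expect_equal(p1$p_value[1], 1 / 2)
  expect_error(pls_permutation(m, n_perm = 0), "positive")
})

test_that("bootstrap ratios separate coupled from uncoupled measures", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 120, n_parcels = 60, n_biomarkers = 10,
                  n_coupled = 4, coupling = 0.9, seed = 14),
    sphere_geometry(60)
  )
  m <- pls_fit(coh$subject_matrix, coh$biomarkers)
  boot <- pls_bootstrap(m, n_boot = 100, seed = 3)
  br <- boot$biomarkers$bootstrap_ratio
  expect_gte(mean(abs(br[1:4]) >= 2), 0.75)
  expect_lte(mean(abs(br[5:10]) >= 2), 0.3)

  # sign alignment: flipping Y's sign flips weights but not |BR|
  m_flip <- pls_fit(coh$subject_matrix, -coh$biomarkers)
  boot_flip <- pls_bootstrap(m_flip, n_boot = 100, seed = 3)
  expect_equal(abs(boot_flip$biomarkers$bootstrap_ratio), abs(br), tolerance = 1e-6)
})

test_that("cross-validation is reproducible and behaves under the null", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 100, n_parcels = 60, n_biomarkers = 8,
                  n_coupled = 4, coupling = 0.8, seed = 15),
    sphere_geometry(60)
  )
  cv1 <- pls_crossval(coh$subject_matrix, coh$biomarkers,
                      n_splits = 1, n_perm = 0, seed = 4)
  cv2 <- pls_crossval(coh$subject_matrix, coh$biomarkers,
                      n_splits = 1, n_perm = 0, seed = 4)
  expect_identical(cv1$mean_r, cv2$mean_r)

  cv <- pls_crossval(coh$subject_matrix, coh$biomarkers,
                     n_splits = 50, n_perm = 99, seed = 5)
  expect_gt(cv$mean_r, 0.2)
  expect_lt(cv$p_value, 0.05)

  # independent blocks: out-of-sample correlation hovers near zero
  set.seed(16)
  x0 <- matrix(rnorm(100 * 30), 100, 30)
  y0 <- matrix(rnorm(100 * 5), 100, 5)
  null_cv <- pls_crossval(x0, y0, n_splits = 50, n_perm = 0, seed = 6)
  expect_lt(abs(null_cv$mean_r), 0.25)

  expect_error(pls_crossval(x0, y0, train_fraction = 1.2), "train_fraction")
})

test_that("mode imputation fills missing biomarkers within group", {
  y <- rbind(c(1, NA), c(1, 5), c(1, 5), c(2, NA), c(2, 7), c(2, 7))
  out <- impute_mode_by_group(y, group = rep(c("a", "b"), each = 3))
  expect_equal(out[1, 2], 5)
  expect_equal(out[4, 2], 7)
})
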