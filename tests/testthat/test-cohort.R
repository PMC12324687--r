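test_that("cohort generation is deterministic and strictly positive", {
  c1 <- simulate_cohort(cohort_config(n_subjects = 30, n_parcels = 50, seed = 5), geom50)
  c2 <- simulate_cohort(cohort_config(n_subjects = 30, n_parcels = 50, seed = 5), geom50)
  expect_identical(c1$subject_matrix, c2$subject_matrix)
  expect_identical(c1$biomarkers, c2$biomarkers)
  expect_true(all(c1$subject_matrix > 0))
  c3 <- simulate_cohort(cohort_config(n_subjects = 30, n_parcels = 50, seed = 6), geom50)
  expect_false(identical(c1$subject_matrix, c3$subject_matrix))
})

test_that("vanishing observation noise recovers the mean surface", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 20, n_parcels = 50, gg_sigma = 1e-6, seed = 2),
    geom50
  )
  rel <- abs(coh$subject_matrix - coh$truth$mu) / coh$truth$mu
  expect_lt(max(rel), 1e-3)
})

test_that("the sex offset is recovered as a log-scale group difference", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 2000, n_parcels = 50, sex_offset = 0.1,
                  base_slope = 0, slope_sd = 0, territory_sd = 0, seed = 3),
    geom50
  )
  lp <- rowMeans(log(coh$subject_matrix))
  diff_f_m <- mean(lp[coh$covariates$sex == 0]) - mean(lp[coh$covariates$sex == 1])
  expect_equal(diff_f_m, 0.1, tolerance = 0.01)
})

test_that("per-parcel OLS slopes on log perfusion recover the planted slope field", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 500, gg_sigma = 0.01, territory_sd = 0, seed = 4),
    sphere_geometry(400)
  )
  glm_tab <- glm_effect_maps(log(coh$subject_matrix), coh$covariates)
  expect_gt(cor(coefficient_map(glm_tab, "age"), coh$truth$slope_map), 0.99)
})

test_that("two disjoint age ranges are supported", {
  coh <- simulate_cohort(
    cohort_config(n_subjects = 300, n_parcels = 50,
                  age_range = list(c(5, 22), c(36, 100)), seed = 8),
    geom50
  )
  a <- coh$covariates$age
  expect_true(all((a >= 5 & a <= 22) | (a >= 36 & a <= 100)))
  expect_true(any(a <= 22) && any(a >= 36))
})

test_that("annotation maps track the target exactly at alpha = 1 and not at alpha = 0", {
  target <- smooth_field(geom100, 0.4, seed = 1)
  ann1 <- simulate_annotations(geom100, target, n_annotations = 30,
                               planted_size = 5, alpha = 1, seed = 2)
  planted <- ann1$categories[[ann1$planted]]
  rs <- cor(t(ann1$maps[planted, ]), target)
  expect_equal(as.vector(rs), rep(1, 5), tolerance = 1e-12)

  # at alpha = 0 the planted members are independent of the target, so
  # their mean |r| must match that of freshly drawn independent fields
  # (the in-test oracle); smooth fields at this lengthscale have few
  # effective spatial degrees of freedom, so neither is near zero
  target400 <- smooth_field(geom400, 0.4, seed = 1)
  mean_abs_r <- mean(vapply(1:100, function(s) {
    a0 <- simulate_annotations(geom400, target400, n_annotations = 10,
                               planted_size = 5, alpha = 0, seed = s)
    mean(abs(cor(t(a0$maps[a0$categories[[a0$planted]], ]), target400)))
  }, numeric(1)))
  indep <- smooth_field(geom400, 0.4, n = 500, seed = 1234)
  oracle <- mean(abs(cor(indep, target400)))
  expect_lt(abs(mean_abs_r - oracle), 0.05)
  expect_lt(mean_abs_r, 0.3)

  expect_error(simulate_annotations(geom100, target, alpha = 1.2), "alpha")
})

test_that("zero donor noise gives differential stability 1 for every annotation", {
  target <- smooth_field(geom50, 0.4, seed = 1)
  ann <- simulate_annotations(geom50, target, n_annotations = 12,
                              planted_size = 4, n_donors = 3, donor_sd = 0,
                              seed = 5)
  ds <- differential_stability(ann$donor_maps)
  expect_equal(ds$ds, rep(1, 12), tolerance = 1e-12)
})

test_that("cohort TSV/JSON export round-trips the subject matrix", {
  dir <- withr::local_tempdir()
  paths <- write_cohort(tiny_cohort, dir)
  tab <- readr::read_tsv(paths[["matrix"]], show_col_types = FALSE)
  expect_equal(as.matrix(tab[, -1]), tiny_cohort$subject_matrix,
               ignore_attr = TRUE, tolerance = 1e-12)
})
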