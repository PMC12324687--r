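test_that("spin assignments: identity rotation, range contract, hand geometry", {
  ens_id <- spin_assignments(geom50, n_null = 1,
                             rotations = list(diag(3)))
  expect_equal(ens_id$assignments[1, ], 1:50)

  ens <- spin_assignments(geom50, n_null = 20, seed = 3)
  expect_true(all(ens$assignments >= 1 & ens$assignments <= 50))

  # 4 equatorial parcels; a 180-degree z-rotation swaps opposite parcels
  eq4 <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  rot180 <- diag(c(-1, -1, 1))
  ens4 <- spin_assignments(eq4, n_null = 1, rotations = list(rot180))
  expect_equal(ens4$assignments[1, ], c(3L, 4L, 1L, 2L))

  expect_error(spin_assignments(geom50, n_null = 0), "positive")
})

test_that("excluded parcels never donate values (medial-wall rule)", {
  excl <- rep(FALSE, 50)
  excl[1:10] <- TRUE
  ens <- spin_assignments(geom50, n_null = 25, seed = 9, exclusion = excl)
  expect_false(any(ens$assignments %in% 1:10))
})

test_that("vasa assignments are bijections and match the documented greedy rule", {
  ens_id <- vasa_assignments(geom50, n_null = 1, rotations = list(diag(3)))
  expect_equal(ens_id$assignments[1, ], 1:50)

  ens <- vasa_assignments(geom50, n_null = 10, seed = 2)
  for (i in 1:10) {
    expect_equal(sort(ens$assignments[i, ]), 1:50)
  }

  # independent re-implementation of the greedy rule on a small instance
  rot <- random_rotation(17)
  coords <- geom50$coords[1:8, ]
  coords <- coords / sqrt(rowSums(coords^2))
  d <- acos(pmin(pmax(tcrossprod(coords, coords %*% t(rot)), -1), 1))
  oracle <- integer(8)
  free_o <- rep(TRUE, 8); free_r <- rep(TRUE, 8)
  dd <- d
  for (step in 1:8) {
    idx <- arrayInd(which.min(ifelse(outer(free_o, free_r, "&"), dd, Inf)), dim(dd))
    oracle[idx[1]] <- idx[2]
    free_o[idx[1]] <- FALSE; free_r[idx[2]] <- FALSE
  }
  got <- vasa_assignments(coords, n_null = 1, rotations = list(rot))
  expect_equal(got$assignments[1, ], oracle)
})

test_that("optimal matching minimizes total distance (brute-force oracle)", {
  set.seed(21)
  cost <- matrix(runif(25), 5, 5)
  a <- solve_assignment(cost)
  got_cost <- sum(cost[cbind(1:5, a)])
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  best <- min(apply(perms, 1, function(p) sum(cost[cbind(1:5, p)])))
  expect_equal(got_cost, best, tolerance = 1e-12)

  # greedy and optimal can disagree, but both stay bijections
  ens_opt <- vasa_assignments(geom50, n_null = 3, seed = 4, method = "optimal")
  for (i in 1:3) expect_equal(sort(ens_opt$assignments[i, ]), 1:50)
})

test_that("variogram surrogates preserve the value multiset and autocorrelation", {
  f <- smooth_field(geom100, 0.4, seed = 6)
  ens <- variogram_surrogates(f, geom100, n_null = 30, seed = 1)
  for (i in c(1, 15, 30)) {
    expect_equal(sort(ens$surrogates[i, ]), sort(f), tolerance = 1e-12)
  }
  expect_error(variogram_surrogates(f, geom100, n_bins = 2), "n_bins")

  # white noise selects the smallest smoothing scale most of the time
  wn <- with(list(), {set.seed(8); rnorm(100)})
  ens_wn <- variogram_surrogates(wn, geom100, n_null = 100, seed = 2)
  expect_gte(mean(ens_wn$selected_scale == min(ens_wn$selected_scale)), 0.8)
})

test_that("inclusive permutation p-values follow the add-one convention", {
  expect_equal(perm_pvalue(1, runif(1000, 0, 0.5), sided = "greater"), 1 / 1001)
  expect_equal(perm_pvalue(0, rep(0.5, 10), sided = "greater"), 1)
  nulls <- c(rep(1, 500), rep(-1, 500))
  expect_equal(perm_pvalue(0.5, nulls, sided = "greater"), 501 / 1001)
  expect_equal(perm_pvalue(0.5, nulls, sided = "two"), 1)
  expect_equal(perm_pvalue(-2, nulls, sided = "less"), 1 / 1001)
  expect_error(perm_pvalue(1, numeric(0)), "non-empty")
})

test_that("spin correlation: self-correlation and near-duplicate force minimum p", {
  ens <- spin_assignments(geom100, n_null = 199, seed = 5)
  f <- smooth_field(geom100, 0.4, seed = 7)
  self <- spin_correlation(f, f, ens)
  expect_equal(self$estimate, 1)
  expect_equal(self$p_spin, 1 / 200)

  noisy <- f + with(list(), {set.seed(1); rnorm(100, sd = 0.05)})
  res <- spin_correlation(f, noisy, ens)
  expect_equal(res$p_spin, 1 / 200)
  expect_error(spin_correlation(rep(1, 100), f, ens), "zero-variance")
})

test_that("null ensembles preserve the value multiset per kind", {
  f <- smooth_field(geom50, 0.4, seed = 4)
  vasa <- vasa_assignments(geom50, n_null = 5, seed = 1)
  nm <- null_maps(vasa, f)
  for (i in 1:5) expect_equal(sort(nm[, i]), sort(f), tolerance = 1e-12)

  spin <- spin_assignments(geom50, n_null = 5, seed = 1)
  nms <- null_maps(spin, f)
  for (i in 1:5) expect_true(all(nms[, i] %in% f)) # sub-multiset: duplicates allowed
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5))$p_adjusted, rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, NA)), "finite")
})
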