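test_that("differential stability: identical, anticorrelated and noisy donors", {
  base <- matrix(smooth_field(geom50, 0.4, n = 3, seed = 1), ncol = 50, byrow = TRUE)
  rownames(base) <- paste0("ann_", 1:3)
  expect_equal(differential_stability(list(base, base, base))$ds, rep(1, 3))

  expect_equal(differential_stability(list(base, -base))$ds, rep(-1, 3))

  # shared + unit noise: DS estimates the shared-variance fraction
  shared_sd <- 1.5
  frac <- shared_sd^2 / (shared_sd^2 + 1)
  ds_hat <- mean(vapply(1:100, function(s) {
    shared <- shared_sd * smooth_field(geom50, 0.4, seed = s)
    donors <- lapply(1:4, function(d) {
      m <- matrix(shared + rnorm(50), 1)
      rownames(m) <- "a"
      m
    })
    differential_stability(donors)$ds
  }, numeric(1)))
  expect_equal(ds_hat, frac, tolerance = 0.05)
})

test_that("category scores: zero, antisymmetric and clipped cases", {
  target <- rep(c(1, 1, -1, -1), 4)
  orth <- rep(c(1, -1), 8) # exactly uncorrelated with target
  expect_equal(category_score(target, rbind(orth)), 0, tolerance = 1e-12)

  member <- target + rep(c(0.3, -0.1), 8)
  expect_equal(category_score(target, rbind(member, -member)), 0, tolerance = 1e-12)

  expect_equal(category_score(target, rbind(target)), atanh(1 - 1e-7))
  expect_error(category_score(target, rbind(rep(2, 16))), "zero-variance")
})

test_that("GCEA detects a planted category and honours the size filter", {
  target <- smooth_field(geom100, 0.4, seed = 10)
  ens <- vasa_assignments(geom100, n_null = 199, seed = 3)
  ann <- simulate_annotations(geom100, target, n_annotations = 100,
                              planted_size = 12, alpha = 0.9,
                              decoy_size = 8, seed = 4)
  tab <- run_gcea(target, ann, ens, min_size = 5)
  expect_equal(tab$category[1], "planted_category") # highest score
  expect_equal(tab$p_value[tab$category == "planted_category"], 1 / 200)

  # categories at or below min_size are absent
  tab_strict <- run_gcea(target, ann, ens, min_size = 8)
  expect_false(any(grepl("decoy", tab_strict$category)))
  expect_error(run_gcea(target, ann, ens, min_size = 50), "retained")

  # output is sorted by score, descending
  expect_true(all(diff(tab$score) <= 1e-12))
})

test_that("DS filtering removes unstable annotations before scoring", {
  target <- smooth_field(geom50, 0.4, seed = 2)
  ann <- simulate_annotations(geom50, target, n_annotations = 20,
                              planted_size = 6, alpha = 0.9,
                              decoy_size = 7, seed = 5)
  ds <- tibble::tibble(annotation = rownames(ann$maps),
                       ds = c(rep(1, 10), rep(0, 10)))
  ens <- vasa_assignments(geom50, n_null = 49, seed = 6)
  tab <- run_gcea(target, ann, ens, min_size = 2, ds = ds, ds_threshold = 0.1)
  # only the first 10 annotations survive: planted keeps 6 members, the
  # first decoy keeps 4 of 7 and is filtered at min_size > 2... sizes shrink
  expect_true(all(tab$n_members <= 10))
  expect_true("planted_category" %in% tab$category)
})

test_that("category files round-trip in TSV and GMT formats", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    category_id = c("a", "a", "b", "b", "b"),
    member = c("g1", "g2", "g3", "g4", "g5")
  ), tsv)
  cats <- read_categories(tsv)
  expect_equal(cats$a, c("g1", "g2"))
  expect_equal(cats$b, c("g3", "g4", "g5"))

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), gmt)
  cats2 <- read_categories(gmt, format = "gmt")
  expect_equal(cats2$setA, c("g1", "g2", "g3"))
  expect_equal(cats2$setB, "g4")
})
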