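# Group-level perfusion maps: subject standardization, the PCA "perfusion
# score map", per-parcel GLM effect maps (age, sex, interactions),
# covariate residualization, connectivity strength and network contrasts.

#' Z-score each subject's map
#'
#' Standardizes every row (subject) of a subjects x locations matrix to
#' mean 0, sample sd 1 (divisor n - 1). Subject-level standardization
#' removes global perfusion offsets (e.g., sex differences in mean
#' perfusion) before pooling.
#'
#' @param matrix subjects x locations numeric matrix.
#' @return Matrix of the same shape.
#' @export
standardize_subjects <- function(matrix) {
  check_matrix(matrix, "matrix")
  zscore_rows(matrix, row_label = "subject")
}

#' Principal-component perfusion score map
#'
#' Singular value decomposition of the (optionally column-centered) matrix
#' of subject-standardized maps. The first right singular vector over
#' locations is the "score map" — the dominant spatial pattern shared
#' across subjects; the first left singular vector holds per-subject
#' loadings. The score map's sign is fixed so it correlates non-negatively
#' with the column mean map.
#'
#' @param matrix subjects x locations matrix; rows should already be
#'   subject-standardized (a warning is emitted otherwise).
#' @param n_components number of components to retain.
#' @param center_columns subtract column means before the SVD? Default
#'   `FALSE`, so the first component can capture the shared mean pattern.
#' @return A `score_map_result`: list with `score_map` (locations),
#'   `subject_loadings` (subjects), `variance_explained` (length
#'   `n_components`, fractions of total variance), and the retained
#'   `components` matrix.
#' @export
pca_score_map <- function(matrix, n_components = 2, center_columns = FALSE) {
  check_matrix(matrix, "matrix")
  if (n_components > min(dim(matrix))) {
    abort("`n_components` exceeds min(n_subjects, n_locations)")
  }
  rm_ <- rowMeans(matrix)
  rs <- apply(matrix, 1L, sd)
  if (max(abs(rm_)) > 1e-8 || max(abs(rs - 1)) > 1e-6) {
    warn("rows do not look subject-standardized; consider standardize_subjects()")
  }
  x <- if (center_columns) sweep(matrix, 2L, colMeans(matrix), "-") else matrix
  sv <- svd(x, nu = n_components, nv = n_components)
  ve <- sv$d^2 / sum(sv$d^2)
  score <- sv$v[, 1]
  load1 <- sv$u[, 1]
  mean_map <- colMeans(matrix)
  if (cor(score, mean_map) < 0) {
    score <- -score
    load1 <- -load1
    sv$v[, 1] <- score
    sv$u[, 1] <- load1
  }
  structure(list(
    score_map = score,
    subject_loadings = load1,
    variance_explained = ve[seq_len(n_components)],
    components = sv$v,
    loadings_matrix = sv$u,
    singular_values = sv$d,
    center_columns = center_columns
  ), class = "score_map_result")
}

#' @export
print.score_map_result <- function(x, ...) {
  cat(sprintf(
    "<score_map_result> PC1 explains %.2f%% of variance (PC2: %.2f%%)\n",
    100 * x$variance_explained[1],
    if (length(x$variance_explained) > 1) 100 * x$variance_explained[2] else NA
  ))
  invisible(x)
}

#' @export
tidy.score_map_result <- function(x, ...) {
  tibble::tibble(
    location = seq_along(x$score_map),
    score = x$score_map
  )
}

#' @export
glance.score_map_result <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$variance_explained),
    variance_explained_pc1 = x$variance_explained[1],
    variance_explained_pc2 = if (length(x$variance_explained) > 1) {
      x$variance_explained[2]
    } else NA_real_
  )
}

# Term vocabulary for perfusion GLMs. `sex` is coded male = 1, female = 0.
glm_term_column <- function(term, covariates) {
  age <- covariates$age
  sex <- covariates$sex
  switch(term,
    "age" = age,
    "sex" = sex,
    "age:sex" = age * sex,
    "age^2" = age^2,
    "sex:age^2" = sex * age^2,
    "age^3" = age^3,
    "sex:age^3" = sex * age^3,
    abort(sprintf("unknown GLM term `%s`", term))
  )
}

build_design <- function(covariates, terms) {
  cols <- lapply(terms, glm_term_column, covariates = covariates)
  x <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(x) <- c("(Intercept)", terms)
  qr_ <- qr(x)
  if (qr_$rank < ncol(x)) {
    dropped <- colnames(x)[qr_$pivot[(qr_$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  x
}

#' Per-location GLM effect maps
#'
#' Fits `value = b0 + b1 age + b2 sex (+ interactions / polynomial terms)`
#' by ordinary least squares independently at every location, with
#' two-sided t-based p-values and a Bonferroni significance mask at
#' family-wise 0.05 (threshold `0.05 / n_locations`).
#'
#' @param matrix subjects x locations matrix.
#' @param covariates tibble with `age` (years) and `sex` (male = 1,
#'   female = 0), rows aligned with the matrix.
#' @param terms character vector of model terms from
#'   `c("age", "sex", "age:sex", "age^2", "sex:age^2", "age^3", "sex:age^3")`.
#' @return A tibble with one row per location x coefficient: `location`,
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`,
#'   `significant_bonferroni`.
#' @export
glm_effect_maps <- function(matrix, covariates, terms = c("age", "sex")) {
  check_matrix(matrix, "matrix")
  stopifnot(nrow(covariates) == nrow(matrix))
  x <- build_design(covariates, terms)
  n <- nrow(x); p <- ncol(x)
  qr_ <- qr(x)
  coefs <- qr.coef(qr_, matrix) # p x locations
  fitted <- x %*% coefs
  resid <- matrix - fitted
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(outer(diag(xtx_inv), sigma2)) # p x locations
  tval <- coefs / se
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  n_loc <- ncol(matrix)
  loc_ids <- if (!is.null(colnames(matrix))) colnames(matrix) else as.character(seq_len(n_loc))
  tibble::tibble(
    location = rep(loc_ids, each = p),
    location_index = rep(seq_len(n_loc), each = p),
    term = rep(rownames(coefs), times = n_loc),
    estimate = as.vector(coefs),
    std_error = as.vector(se),
    statistic = as.vector(tval),
    p_value = as.vector(pval),
    significant_bonferroni = as.vector(pval) < 0.05 / n_loc
  )
}

#' Extract one coefficient's spatial map from a GLM result
#'
#' @param glm_table output of [glm_effect_maps()].
#' @param term coefficient name, e.g. `"age"`.
#' @return Numeric vector over locations, in location order.
#' @export
coefficient_map <- function(glm_table, term = "age") {
  rows <- glm_table[glm_table$term == term, ]
  if (!nrow(rows)) abort(sprintf("term `%s` not present in the GLM table", term))
  rows$estimate[order(rows$location_index)]
}

#' Residualize covariate effects out of a subject matrix
#'
#' Fits, at each location, a cubic-polynomial age model with full sex
#' interactions
#' `b0 + b1 age + b2 sex + b3 sex:age + b4 age^2 + b5 sex:age^2 + b6 age^3 + b7 sex:age^3`
#' and returns the residuals (observed minus fitted).
#'
#' @inheritParams glm_effect_maps
#' @param terms model terms; default is the full degree-3 sex-interaction
#'   design above.
#' @return Residual matrix, same shape as `matrix`; residuals are
#'   orthogonal to every design column.
#' @export
residualize_covariates <- function(matrix, covariates,
                                   terms = c("age", "sex", "age:sex", "age^2",
                                             "sex:age^2", "age^3", "sex:age^3")) {
  check_matrix(matrix, "matrix")
  stopifnot(nrow(covariates) == nrow(matrix))
  x <- build_design(covariates, terms)
  # Householder projection keeps residuals orthogonal to the design even
  # for badly scaled cubic age columns
  qr.resid(qr(x), matrix)
}

#' Connectivity strength map
#'
#' Per-node sum of absolute edge weights, diagonal excluded — the
#' "hubness" summary applied to functional connectivity matrices.
#'
#' @param connectivity square locations x locations weight matrix.
#' @return Numeric vector of strengths.
#' @export
strength_map <- function(connectivity) {
  check_matrix(connectivity, "connectivity")
  if (nrow(connectivity) != ncol(connectivity)) {
    abort("`connectivity` must be square")
  }
  w <- abs(connectivity)
  diag(w) <- 0
  colSums(w)
}

#' Contrast a map between two location groups, with a spin null
#'
#' Computes the group mean difference of a spatial map (e.g., the linear
#' age coefficient stratified into unimodal vs transmodal cortex), a Welch
#' t-test, and a spatial-autocorrelation-preserving permutation p-value
#' obtained by recomputing the difference with the map's values spun over
#' locations while the labels stay fixed.
#'
#' @param map numeric vector over locations.
#' @param labels logical or two-level vector; `TRUE` (or the first level) is
#'   group A.
#' @param ensemble a [null_ensemble] from [spin_assignments()] or
#'   [vasa_assignments()] (or surrogate maps from [variogram_surrogates()]).
#' @param sided `"two"` (default) or `"greater"`/`"less"` for the spin test.
#' @return A one-row tibble: `delta` (mean A - mean B), `statistic` (Welch
#'   t), `p_parametric`, `p_spin`, `n_null`.
#' @export
network_contrast <- function(map, labels, ensemble = NULL, sided = "two") {
  if (is.logical(labels)) {
    a <- labels
  } else {
    lv <- unique(labels)
    if (length(lv) != 2) abort("`labels` must have exactly two levels")
    a <- labels == lv[1]
  }
  if (!any(a) || all(a)) abort("both label groups must be non-empty")
  if (length(map) != length(labels)) abort("`map` and `labels` lengths differ")
  delta <- mean(map[a]) - mean(map[!a])
  tt <- t.test(map[a], map[!a])
  p_spin <- NA_real_
  n_null <- 0L
  if (!is.null(ensemble)) {
    nulls <- null_maps(ensemble, map)
    delta_null <- colMeans(nulls[a, , drop = FALSE]) -
      colMeans(nulls[!a, , drop = FALSE])
    p_spin <- perm_pvalue(delta, delta_null, sided = sided)
    n_null <- ensemble$n_null
  }
  tibble::tibble(
    delta = delta,
    statistic = unname(tt$statistic),
    p_parametric = tt$p.value,
    p_spin = p_spin,
    n_null = n_null
  )
}
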