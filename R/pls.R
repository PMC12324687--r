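# Behavioral partial least squares: SVD of the cross-correlation matrix
# between column-standardized perfusion maps (X) and biomarkers (Y).
# Each singular triplet is a latent variable; subjects get brain scores XU
# and biomarker scores YV; covariance explained is the squared singular
# value fraction. Inference is by row permutation (singular values),
# bootstrap resampling (weight stability) and train/test cross-validation
# (generalizability).

#' Impute missing biomarker values by within-group mode
#'
#' Replaces `NA`s in each column with the most frequent observed value
#' inside the subject's group (typically biological sex).
#'
#' @param y subjects x measures matrix, possibly with `NA`s.
#' @param group grouping vector of length `nrow(y)`.
#' @return The imputed matrix.
#' @export
impute_mode_by_group <- function(y, group) {
  stats_mode <- function(v) {
    v <- v[!is.na(v)]
    ux <- unique(v)
    ux[which.max(tabulate(match(v, ux)))]
  }
  for (g in unique(group)) {
    rows <- which(group == g)
    for (j in seq_len(ncol(y))) {
      miss <- rows[is.na(y[rows, j])]
      if (length(miss)) y[miss, j] <- stats_mode(y[rows, j])
    }
  }
  if (anyNA(y)) abort("imputation left missing values (a group is all-NA for some measure)")
  y
}

#' Fit a behavioral PLS model
#'
#' Columns of both blocks are z-scored; the cross-block matrix
#' `R = X'Y` (locations x measures) is decomposed as `R = U S V'`. Brain
#' scores are `XU`, biomarker scores `YV`; loadings are the Pearson
#' correlations of each original column with its latent-variable score.
#'
#' @param x_raw subjects x locations matrix.
#' @param y_raw subjects x measures matrix (impute missing values first,
#'   see [impute_mode_by_group()]).
#' @param n_components latent variables to retain (default: all).
#' @return A `pls_model`: `u` (locations x k), `v` (measures x k),
#'   `singular_values`, `covariance_explained`, `brain_scores`,
#'   `biomarker_scores`, `brain_loadings`, `biomarker_loadings`, plus the
#'   standardized blocks for resampling.
#' @export
pls_fit <- function(x_raw, y_raw, n_components = NULL) {
  check_matrix(x_raw, "x_raw"); check_matrix(y_raw, "y_raw")
  if (nrow(x_raw) != nrow(y_raw)) abort("X and Y must have the same subjects")
  if (nrow(x_raw) < 3) abort("need at least 3 subjects")
  x <- zscore_cols(x_raw)
  y <- zscore_cols(y_raw)
  r <- crossprod(x, y)
  k_max <- min(dim(r))
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  sv <- svd(r)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  brain_scores <- x %*% u
  biomarker_scores <- y %*% v
  brain_loadings <- cor(x_raw, brain_scores)
  biomarker_loadings <- cor(y_raw, biomarker_scores)
  rownames(v) <- colnames(y_raw)
  structure(list(
    u = u, v = v,
    singular_values = sv$d,
    covariance_explained = sv$d^2 / sum(sv$d^2),
    brain_scores = brain_scores,
    biomarker_scores = biomarker_scores,
    brain_loadings = brain_loadings,
    biomarker_loadings = biomarker_loadings,
    x = x, y = y, x_raw = x_raw, y_raw = y_raw,
    n_components = k
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> %d subjects, %d locations x %d measures; LV1 covariance explained %.1f%%\n",
    nrow(x$x), nrow(x$u), nrow(x$v), 100 * x$covariance_explained[1]
  ))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, component = 1, ...) {
  tibble::tibble(
    measure = rownames(x$v) %||% as.character(seq_len(nrow(x$v))),
    weight = x$v[, component],
    loading = x$biomarker_loadings[, component]
  )
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$x),
    n_locations = nrow(x$u),
    n_measures = nrow(x$v),
    covariance_explained_lv1 = x$covariance_explained[1]
  )
}

#' Permutation test on PLS singular values
#'
#' Rows of X are randomly permuted, the cross-block matrix rebuilt and
#' re-decomposed; each latent variable's p-value is the inclusive
#' probability that the permuted k-th singular value reaches the observed
#' one (ordered comparison).
#'
#' @param model a `pls_model`.
#' @param n_perm number of permutations.
#' @param seed master seed.
#' @param shuffle which block's rows to permute (`"x"`, the convention
#'   here, or `"y"`; equivalent in distribution).
#' @return A tibble: `component`, `singular_value`, `covariance_explained`,
#'   `p_value`.
#' @export
pls_permutation <- function(model, n_perm = 1000, seed = 1L, shuffle = c("x", "y")) {
  shuffle <- match.arg(shuffle)
  if (n_perm <= 0) abort("`n_perm` must be positive")
  k <- model$n_components
  obs <- model$singular_values[seq_len(k)]
  null_d <- matrix(0, n_perm, k)
  n <- nrow(model$x)
  for (b in seq_len(n_perm)) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n))
    r <- if (shuffle == "x") {
      crossprod(model$x[idx, , drop = FALSE], model$y)
    } else {
      crossprod(model$x, model$y[idx, , drop = FALSE])
    }
    null_d[b, ] <- svd(r, nu = 0, nv = 0)$d[seq_len(k)]
  }
  tibble::tibble(
    component = seq_len(k),
    singular_value = obs,
    covariance_explained = model$covariance_explained[seq_len(k)],
    p_value = vapply(seq_len(k), function(j) {
      perm_pvalue(obs[j], null_d[, j], sided = "greater")
    }, numeric(1))
  )
}

#' Bootstrap ratios for PLS weights
#'
#' Subjects are resampled with replacement and the model refitted; each
#' weight's bootstrap ratio is the original weight divided by its bootstrap
#' standard error. Resampled singular vectors are sign-aligned to the
#' original by the sign of their inner product before pooling.
#'
#' @param model a `pls_model`.
#' @param n_boot number of bootstrap resamples.
#' @param seed master seed.
#' @param component latent variable to summarize.
#' @return A list with tibbles `biomarkers` (`measure`, `weight`,
#'   `boot_se`, `bootstrap_ratio`) and `locations` (same columns per
#'   location). A zero bootstrap sd yields a signed infinite ratio with a
#'   warning.
#' @export
pls_bootstrap <- function(model, n_boot = 1000, seed = 1L, component = 1) {
  if (n_boot <= 0) abort("`n_boot` must be positive")
  n <- nrow(model$x_raw)
  u0 <- model$u[, component]
  v0 <- model$v[, component]
  boot_u <- matrix(0, length(u0), n_boot)
  boot_v <- matrix(0, length(v0), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n, replace = TRUE))
    xb <- zscore_cols(model$x_raw[idx, , drop = FALSE])
    yb <- zscore_cols(model$y_raw[idx, , drop = FALSE])
    sv <- svd(crossprod(xb, yb), nu = component, nv = component)
    ub <- sv$u[, component]
    vb <- sv$v[, component]
    s <- sign(sum(ub * u0) + sum(vb * v0))
    if (s == 0) s <- 1
    boot_u[, b] <- s * ub
    boot_v[, b] <- s * vb
  }
  se_u <- apply(boot_u, 1L, sd)
  se_v <- apply(boot_v, 1L, sd)
  if (any(se_u == 0) || any(se_v == 0)) {
    warn("zero bootstrap sd for some weights; bootstrap ratio reported as signed Inf")
  }
  ratio <- function(w, se) ifelse(se == 0, sign(w) * Inf, w / se)
  list(
    biomarkers = tibble::tibble(
      measure = rownames(model$v) %||% as.character(seq_along(v0)),
      weight = v0, boot_se = se_v, bootstrap_ratio = ratio(v0, se_v)
    ),
    locations = tibble::tibble(
      location = seq_along(u0),
      weight = u0, boot_se = se_u, bootstrap_ratio = ratio(u0, se_u)
    )
  )
}

pls_one_split <- function(x_raw, y_raw, train_fraction, split_seed) {
  n <- nrow(x_raw)
  n_train <- round(train_fraction * n)
  if (n - n_train < 3) abort("test split must keep at least 3 subjects")
  idx <- with_seed(split_seed, sample.int(n))
  tr <- idx[seq_len(n_train)]
  te <- idx[-seq_len(n_train)]
  xm <- colMeans(x_raw[tr, , drop = FALSE]); xs <- apply(x_raw[tr, , drop = FALSE], 2, sd)
  ym <- colMeans(y_raw[tr, , drop = FALSE]); ys <- apply(y_raw[tr, , drop = FALSE], 2, sd)
  if (any(xs == 0) || any(ys == 0)) return(NA_real_)
  xtr <- sweep(sweep(x_raw[tr, , drop = FALSE], 2, xm), 2, xs, "/")
  ytr <- sweep(sweep(y_raw[tr, , drop = FALSE], 2, ym), 2, ys, "/")
  sv <- svd(crossprod(xtr, ytr), nu = 1, nv = 1)
  xte <- sweep(sweep(x_raw[te, , drop = FALSE], 2, xm), 2, xs, "/")
  yte <- sweep(sweep(y_raw[te, , drop = FALSE], 2, ym), 2, ys, "/")
  cor(xte %*% sv$u[, 1], yte %*% sv$v[, 1])[1]
}

#' Cross-validated PLS score correlation
#'
#' Random train/test splits: the model is fitted on the training fraction
#' (column statistics from training data only), test subjects are projected
#' onto the training weights, and the Pearson correlation between test
#' brain and biomarker scores for the first latent variable is recorded.
#' Significance comes from a permutation null in which X rows are shuffled
#' before splitting; `p = (1 + #null >= observed mean) / (1 + n_perm)`.
#'
#' @param x_raw,y_raw subject-aligned data blocks.
#' @param train_fraction fraction of subjects used for training (default
#'   0.8).
#' @param n_splits number of random train/test splits.
#' @param n_perm number of permutations (one shuffled split each).
#' @param seed master seed.
#' @return A `pls_crossval` list: `mean_r`, `split_r` (length `n_splits`),
#'   `null_r`, `p_value`.
#' @export
pls_crossval <- function(x_raw, y_raw, train_fraction = 0.8, n_splits = 1000,
                         n_perm = 1000, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly inside (0, 1)")
  }
  check_matrix(x_raw, "x_raw"); check_matrix(y_raw, "y_raw")
  split_r <- vapply(seq_len(n_splits), function(b) {
    pls_one_split(x_raw, y_raw, train_fraction, derive_seed(seed, b))
  }, numeric(1))
  mean_r <- mean(split_r, na.rm = TRUE)
  null_r <- NULL
  p_value <- NA_real_
  if (n_perm > 0) {
    n <- nrow(x_raw)
    null_r <- vapply(seq_len(n_perm), function(b) {
      sd_ <- derive_seed(seed, n_splits + 2L * b)
      idx <- with_seed(sd_, sample.int(n))
      pls_one_split(x_raw[idx, , drop = FALSE], y_raw, train_fraction,
                    derive_seed(seed, n_splits + 2L * b + 1L))
    }, numeric(1))
    p_value <- perm_pvalue(mean_r, null_r[!is.na(null_r)], sided = "greater")
  }
  structure(list(mean_r = mean_r, split_r = split_r, null_r = null_r,
                 p_value = p_value, train_fraction = train_fraction),
            class = "pls_crossval")
}

#' @export
print.pls_crossval <- function(x, ...) {
  cat(sprintf("<pls_crossval> mean out-of-sample r = %.3f (p = %.4g, %d splits)\n",
              x$mean_r, x$p_value, length(x$split_r)))
  invisible(x)
}
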