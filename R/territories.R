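# Inter-subject perfusion covariance and its diffusion-map gradients.
# Locations whose perfusion co-varies across subjects (e.g., parcels fed
# by the same arterial territory) form blocks in the covariance graph; the
# leading diffusion-embedding eigen-maps ("gradients") recover them.

#' Inter-subject perfusion covariance graph
#'
#' Subject maps are z-scored within subject (rows), then each location is
#' z-scored across subjects (columns), and the location x location Pearson
#' correlation across subjects is computed on the doubly standardized data.
#'
#' @param matrix subjects x locations matrix (>= 3 subjects).
#' @return A `covariance_graph`: list with `matrix` (location x location,
#'   unit diagonal) and `location` ids.
#' @export
perfusion_covariance <- function(matrix) {
  check_matrix(matrix, "matrix")
  if (nrow(matrix) < 3) abort("need at least 3 subjects")
  x <- zscore_rows(matrix, "subject")
  x <- zscore_cols(x)
  cc <- cor(x)
  structure(list(
    matrix = cc,
    location = colnames(matrix) %||% as.character(seq_len(ncol(matrix)))
  ), class = "covariance_graph")
}

graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Diffusion-map gradients of a covariance graph
#'
#' Keeps, per row, the top `(1 - sparsity)` fraction of entries, builds a
#' non-negative affinity from the sparsified rows, alpha-normalizes
#' (`W / (d^alpha d^alpha')`, `alpha = 0.5` gives Fokker-Planck scaling),
#' row-normalizes to a Markov transition operator and eigendecomposes it.
#' The trivial constant eigenvector is dropped; gradients are the next
#' `n_components` right eigenvectors scaled by their eigenvalues. Each
#' gradient's sign is fixed so its largest-magnitude loading is positive.
#'
#' Two affinity kernels are available. `"normalized_angle"` (default, the
#' convention of diffusion-embedding toolboxes) uses
#' `1 - acos(cosine similarity of sparsified rows) / pi`, which is strictly
#' positive and keeps anticorrelated blocks weakly connected. `"clip"`
#' takes the sparsified entries themselves with negatives clipped to zero;
#' it is simpler but disconnects when two blocks are anticorrelated — as
#' doubly z-scored two-territory covariance always is — and then errors.
#'
#' @param graph a `covariance_graph` or a square affinity/correlation
#'   matrix.
#' @param n_components number of gradients (default 5).
#' @param alpha diffusion alpha-normalization exponent (default 0.5).
#' @param sparsity per-row fraction of smallest entries zeroed before
#'   embedding (default 0.9).
#' @param kernel `"normalized_angle"` (default) or `"clip"`.
#' @return A `gradient_result`: `gradients` (location x k), `lambdas`
#'   (non-increasing eigenvalues), and the embedding parameters.
#' @export
diffusion_gradients <- function(graph, n_components = 5, alpha = 0.5,
                                sparsity = 0.9,
                                kernel = c("normalized_angle", "clip")) {
  kernel <- match.arg(kernel)
  cc <- if (inherits(graph, "covariance_graph")) graph$matrix else graph
  check_matrix(cc, "graph")
  n <- nrow(cc)
  if (n != ncol(cc)) abort("affinity must be square")
  w <- cc
  if (sparsity > 0) {
    keep <- max(1L, ceiling((1 - sparsity) * n))
    for (i in seq_len(n)) {
      thr <- sort(w[i, ], decreasing = TRUE)[keep]
      w[i, w[i, ] < thr] <- 0
    }
  }
  if (kernel == "normalized_angle") {
    nrm <- sqrt(rowSums(w^2))
    if (any(nrm == 0)) abort("a row became all-zero after sparsification; lower `sparsity`")
    cs <- tcrossprod(w / nrm)
    w <- 1 - acos(pmin(pmax(cs, -1), 1)) / pi
  } else {
    w[w < 0] <- 0
    w <- (w + t(w)) / 2
  }
  diag(w) <- 0
  if (!graph_connected(w)) {
    abort("affinity graph is disconnected after sparsification; lower `sparsity`")
  }
  deg <- rowSums(w)
  w_a <- w / outer(deg^alpha, deg^alpha)
  d_a <- rowSums(w_a)
  # symmetric conjugate of the transition operator for a stable eigensolve
  s <- w_a / outer(sqrt(d_a), sqrt(d_a))
  es <- eigen(s, symmetric = TRUE)
  psi <- es$vectors / sqrt(d_a) # right eigenvectors of D^-1 W_alpha
  lambdas <- es$values[2:(n_components + 1)]
  grads <- psi[, 2:(n_components + 1), drop = FALSE]
  grads <- sweep(grads, 2L, lambdas, "*")
  for (j in seq_len(ncol(grads))) {
    i_max <- which.max(abs(grads[, j]))
    if (grads[i_max, j] < 0) grads[, j] <- -grads[, j]
  }
  structure(list(
    gradients = grads,
    lambdas = lambdas,
    alpha = alpha,
    sparsity = sparsity,
    kernel = kernel,
    location = if (inherits(graph, "covariance_graph")) graph$location else NULL
  ), class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result> %d gradients; lambdas: %s\n",
              ncol(x$gradients),
              paste(sprintf("%.3f", x$lambdas), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.gradient_result <- function(x, ...) {
  g <- tibble::as_tibble(x$gradients, .name_repair = ~ sprintf("gradient_%d", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(location = x$location %||% as.character(seq_len(nrow(x$gradients)))),
    g
  )
}

#' Annotate gradients with term maps under a spatial null
#'
#' Correlates every term map with gradients 1 and 2; a term is flagged
#' significant when its correlation passes the two-sided spatial-null
#' threshold at 0.05 on either axis.
#'
#' @param result a `gradient_result`.
#' @param term_maps terms x locations matrix (row names = term labels).
#' @param ensemble a `null_ensemble` over the same locations.
#' @return A tibble: `term`, `r1`, `p1`, `r2`, `p2`, `significant`.
#'   Zero-variance term maps are skipped with a warning.
#' @export
annotate_gradients <- function(result, term_maps, ensemble) {
  g1 <- result$gradients[, 1]
  g2 <- result$gradients[, 2]
  keep <- apply(term_maps, 1L, sd) > 0
  if (any(!keep)) {
    warn(sprintf("skipping %d zero-variance term map(s)", sum(!keep)))
    term_maps <- term_maps[keep, , drop = FALSE]
  }
  null_g1 <- null_maps(ensemble, g1)
  null_g2 <- null_maps(ensemble, g2)
  tm <- t(term_maps) # locations x terms
  r1 <- as.vector(cor(tm, g1))
  r2 <- as.vector(cor(tm, g2))
  nr1 <- cor(tm, null_g1) # terms x n_null
  nr2 <- cor(tm, null_g2)
  p1 <- vapply(seq_len(nrow(term_maps)), function(i) {
    perm_pvalue(r1[i], nr1[i, ], sided = "two")
  }, numeric(1))
  p2 <- vapply(seq_len(nrow(term_maps)), function(i) {
    perm_pvalue(r2[i], nr2[i, ], sided = "two")
  }, numeric(1))
  tibble::tibble(
    term = rownames(term_maps) %||% as.character(seq_len(nrow(term_maps))),
    r1 = r1, p1 = p1, r2 = r2, p2 = p2,
    significant = p1 < 0.05 | p2 < 0.05
  )
}
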