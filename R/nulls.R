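# Spatial-autocorrelation-preserving null models. Naive permutation tests
# on brain maps are anticonservative because neighbouring parcels are
# correlated; these nulls randomize a map's spatial embedding while
# preserving its values and autocorrelation, and feed every permutation
# p-value in the package.

new_null_ensemble <- function(kind, assignments = NULL, surrogates = NULL,
                              seed = NULL, n_parcels, source_map = NULL) {
  structure(list(
    kind = kind,
    assignments = assignments,
    surrogates = surrogates,
    n_null = if (!is.null(assignments)) nrow(assignments) else nrow(surrogates),
    n_parcels = n_parcels,
    seed = seed,
    source_map = source_map
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> kind=%s, %d nulls x %d parcels\n",
              x$kind, x$n_null, x$n_parcels))
  invisible(x)
}

get_centroids <- function(geometry) {
  if (inherits(geometry, "sphere_geometry")) geometry$coords else {
    check_matrix(geometry, "centroids")
    geometry
  }
}

# One spin: rotate centroids, then give every original parcel the value of
# the nearest rotated parcel (duplicates allowed). Rotated parcels flagged
# in `exclusion` (the medial-wall analog) are skipped: the next closest
# non-excluded parcel is used instead. In mirror mode the right hemisphere
# receives the x-reflected rotation M R M and matching stays within
# hemisphere, preserving the published two-hemisphere convention.
spin_once <- function(coords, rotation, exclusion = NULL, hemisphere = NULL) {
  n <- nrow(coords)
  assign_block <- function(idx, rot) {
    rotated <- coords[idx, , drop = FALSE] %*% t(rot)
    dots <- tcrossprod(coords[idx, , drop = FALSE], rotated) # original x rotated
    if (!is.null(exclusion) && any(exclusion[idx])) {
      dots[, exclusion[idx]] <- -Inf # excluded rotated parcels never donate
    }
    idx[max.col(dots, ties.method = "first")]
  }
  out <- integer(n)
  if (is.null(hemisphere)) {
    out <- assign_block(seq_len(n), rotation)
  } else {
    m <- diag(c(-1, 1, 1))
    for (h in unique(hemisphere)) {
      idx <- which(hemisphere == h)
      rot <- if (h == sort(unique(hemisphere))[1]) rotation else m %*% rotation %*% m
      out[idx] <- assign_block(idx, rot)
    }
  }
  out
}

#' Spin null ensemble (nearest rotated parcel reassignment)
#'
#' For each null, parcel centroid coordinates are rotated by a Haar-uniform
#' random rotation and every original parcel takes the value of the closest
#' rotated parcel (the same rotated parcel may donate to several originals).
#'
#' @param geometry a [sphere_geometry()] or an `n x 3` centroid matrix.
#' @param n_null ensemble size.
#' @param seed master seed; null `i` uses a child seed derived from it, so
#'   the ensemble is reproducible and order-independent.
#' @param mirror if `TRUE`, rotate the two hemispheres with mirrored
#'   rotations (x-axis reflection), matching within hemisphere; requires a
#'   `sphere_geometry` with hemisphere tags.
#' @param exclusion optional logical mask of parcels standing in for the
#'   medial wall: a rotated parcel in the mask never donates its value, the
#'   next closest is used.
#' @param rotations optional list of rotation matrices overriding the
#'   random draws (testing hook).
#' @return A `null_ensemble` with an `n_null x n_parcels` assignment matrix;
#'   row `i`, entry `j` is the parcel whose value parcel `j` receives.
#' @export
spin_assignments <- function(geometry, n_null = 1000, seed = 1L,
                             mirror = FALSE, exclusion = NULL,
                             rotations = NULL) {
  if (n_null <= 0) abort("`n_null` must be positive")
  coords <- get_centroids(geometry)
  if (nrow(coords) < 2) abort("need at least 2 parcels")
  hemi <- if (mirror) {
    if (!inherits(geometry, "sphere_geometry")) {
      abort("mirror mode needs a sphere_geometry with hemisphere tags")
    }
    geometry$parcels$hemisphere
  } else NULL
  assignments <- matrix(0L, n_null, nrow(coords))
  for (i in seq_len(n_null)) {
    rot <- if (!is.null(rotations)) rotations[[i]] else {
      random_rotation(derive_seed(seed, i))
    }
    assignments[i, ] <- spin_once(coords, rot, exclusion, hemi)
  }
  new_null_ensemble("spin", assignments = assignments, seed = seed,
                    n_parcels = nrow(coords))
}

# Greedy unique matching: walk (original, rotated) pairs by ascending
# great-circle distance, accepting a pair when both sides are still free;
# ties resolve to the lowest column-major index.
greedy_unique_match <- function(dist) {
  n <- nrow(dist)
  ord <- order(dist) # stable: ties by lowest linear (column-major) index
  assign <- integer(n)
  orig_free <- rep(TRUE, n)
  rot_free <- rep(TRUE, n)
  left <- n
  for (e in ord) {
    j <- ((e - 1L) %% n) + 1L # original (row)
    k <- ((e - 1L) %/% n) + 1L # rotated (column)
    if (orig_free[j] && rot_free[k]) {
      assign[j] <- k
      orig_free[j] <- FALSE
      rot_free[k] <- FALSE
      left <- left - 1L
      if (left == 0L) break
    }
  }
  assign
}

#' Váša-style null ensemble (bijective parcel reassignment)
#'
#' Like [spin_assignments()], but the original-to-rotated matching is
#' forced to be one-to-one, so every null map is a true permutation of the
#' original values. The default matching is greedy by ascending distance
#' with uniqueness enforced; `method = "optimal"` solves the minimum-cost
#' assignment instead.
#'
#' @inheritParams spin_assignments
#' @param method `"greedy"` (default) or `"optimal"` (Jonker-Volgenant
#'   minimum total distance).
#' @return A `null_ensemble` whose assignment rows are permutations of
#'   `1:n_parcels`.
#' @export
vasa_assignments <- function(geometry, n_null = 1000, seed = 1L,
                             method = c("greedy", "optimal"),
                             rotations = NULL) {
  method <- match.arg(method)
  if (n_null <= 0) abort("`n_null` must be positive")
  coords <- get_centroids(geometry)
  n <- nrow(coords)
  if (n < 2) abort("need at least 2 parcels")
  assignments <- matrix(0L, n_null, n)
  for (i in seq_len(n_null)) {
    rot <- if (!is.null(rotations)) rotations[[i]] else {
      random_rotation(derive_seed(seed, i))
    }
    rotated <- coords %*% t(rot)
    d <- acos(pmin(pmax(tcrossprod(coords, rotated), -1), 1))
    assignments[i, ] <- if (method == "greedy") {
      greedy_unique_match(d)
    } else {
      solve_assignment(d)
    }
  }
  new_null_ensemble("vasa", assignments = assignments, seed = seed,
                    n_parcels = n)
}

binned_variogram <- function(x, pair_i, pair_j, bin_index, n_bins) {
  d2 <- 0.5 * (x[pair_i] - x[pair_j])^2
  as.vector(rowsum(d2, bin_index, reorder = TRUE)) / tabulate(bin_index, n_bins)
}

#' Variogram-matched surrogate maps
#'
#' Generative null for geometries without spherical centroids: each
#' surrogate permutes the source map's values, smooths them with a Gaussian
#' kernel of geodesic distance over a grid of candidate scales, keeps the
#' scale whose binned semivariogram best matches the source map's, then
#' rank-remaps the smoothed values onto the original value multiset — so
#' every surrogate has exactly the source values with near-matching spatial
#' autocorrelation.
#'
#' Within each of `n_restarts` random permutations, the smoothing scale is
#' chosen by weighted least squares of the source variogram on the
#' candidate's variogram over the distance bins (weights `1/gamma^2`, so
#' the short-range bins that carry the autocorrelation are matched tightly;
#' for a white-noise source this selects the smallest scale). The restart
#' whose finished surrogate has the smallest mean relative variogram
#' deviation from the source is kept.
#'
#' @param map numeric source map over parcels.
#' @param distances parcel x parcel geodesic distance matrix (radians) or a
#'   `sphere_geometry`.
#' @param n_null number of surrogates.
#' @param seed master seed.
#' @param n_bins equal-count distance bins for the variogram (>= 3).
#' @param n_scales geometric grid of candidate smoothing scales spanning
#'   `[min positive distance, pi/2]`.
#' @param n_restarts random permutation restarts per surrogate; the best-
#'   matching one is kept.
#' @return A `null_ensemble` of kind `"variogram"` carrying the surrogate
#'   maps (`n_null x n_parcels`).
#' @export
variogram_surrogates <- function(map, distances, n_null = 1000, seed = 1L,
                                 n_bins = 25, n_scales = 10, n_restarts = 5) {
  if (inherits(distances, "sphere_geometry")) distances <- distances$distances
  if (n_bins < 3) abort("`n_bins` must be at least 3")
  if (any(!is.finite(map))) abort("`map` must be finite")
  n <- length(map)
  stopifnot(nrow(distances) == n, ncol(distances) == n)

  ut <- which(upper.tri(distances))
  pair_i <- ((ut - 1L) %% n) + 1L
  pair_j <- ((ut - 1L) %/% n) + 1L
  dpairs <- distances[ut]
  qs <- quantile(dpairs, probs = seq(0, 1, length.out = n_bins + 1))
  bin_index <- findInterval(dpairs, qs[-c(1, n_bins + 1)]) + 1L

  dmin <- min(dpairs[dpairs > 0])
  scales <- exp(seq(log(dmin), log(pi / 2), length.out = n_scales))
  kernels <- lapply(scales, function(s) {
    k <- exp(-distances^2 / (2 * s^2))
    k / rowSums(k)
  })

  gamma_src <- binned_variogram(map, pair_i, pair_j, bin_index, n_bins)
  sorted_vals <- sort(map)
  wts <- 1 / gamma_src^2

  surrogates <- matrix(0, n_null, n)
  selected_scale <- numeric(n_null)
  for (b in seq_len(n_null)) {
    best_dev <- Inf
    for (r in seq_len(n_restarts)) {
      perm <- with_seed(derive_seed(seed, (b - 1L) * n_restarts + r),
                        sample.int(n))
      xp <- map[perm]
      best_err <- Inf
      best_sm <- NULL
      cand_scale <- NA_real_
      for (s in seq_len(n_scales)) {
        sm <- as.vector(kernels[[s]] %*% xp)
        sm <- (sm - mean(sm)) / sd(sm)
        gamma_s <- binned_variogram(sm, pair_i, pair_j, bin_index, n_bins)
        slope <- sum(wts * gamma_s * gamma_src) / sum(wts * gamma_s^2)
        err <- sum(wts * (slope * gamma_s - gamma_src)^2)
        if (err < best_err) {
          best_err <- err
          best_sm <- sm
          cand_scale <- scales[s]
        }
      }
      sur <- sorted_vals[rank(best_sm, ties.method = "first")]
      dev <- mean(abs(binned_variogram(sur, pair_i, pair_j, bin_index, n_bins) -
                        gamma_src) / gamma_src)
      if (dev < best_dev) {
        best_dev <- dev
        surrogates[b, ] <- sur
        selected_scale[b] <- cand_scale
      }
    }
  }
  ens <- new_null_ensemble("variogram", surrogates = surrogates, seed = seed,
                           n_parcels = n, source_map = map)
  ens$selected_scale <- selected_scale
  ens
}

#' Materialize null maps from an ensemble
#'
#' @param ensemble a `null_ensemble`.
#' @param map the map to randomize (spin/vasa kinds); for variogram
#'   ensembles the surrogates were built from a fixed source map, which must
#'   match.
#' @return locations x n_null matrix of null maps.
#' @export
null_maps <- function(ensemble, map) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$kind == "variogram") {
    if (!isTRUE(all.equal(as.numeric(map), as.numeric(ensemble$source_map)))) {
      abort("variogram ensembles are tied to their source map; rebuild with variogram_surrogates()")
    }
    return(t(ensemble$surrogates))
  }
  if (length(map) != ensemble$n_parcels) {
    abort("`map` length does not match the ensemble's parcel count")
  }
  matrix(map[t(ensemble$assignments)], length(map), ensemble$n_null)
}

#' Inclusive permutation p-value
#'
#' Add-one counting convention: `p = (1 + #extreme nulls) / (1 + n_null)`,
#' so the smallest attainable p with 1000 nulls is 1/1001 = 9.99e-4 and p
#' is never zero.
#'
#' @param observed scalar observed statistic.
#' @param null_samples vector of null statistics.
#' @param sided `"greater"`, `"less"`, or `"two"` (compares absolute
#'   values).
#' @return The p-value.
#' @export
perm_pvalue <- function(observed, null_samples, sided = c("greater", "less", "two")) {
  sided <- match.arg(sided)
  if (!length(null_samples)) abort("`null_samples` must be non-empty")
  extreme <- switch(sided,
    greater = sum(null_samples >= observed),
    less = sum(null_samples <= observed),
    two = sum(abs(null_samples) >= abs(observed))
  )
  (1 + extreme) / (1 + length(null_samples))
}

#' Spatial-null correlation test between two maps
#'
#' Pearson correlation of two parcel maps, tested against a null
#' distribution in which `map_a` is replaced by each null realization from
#' the ensemble while `map_b` stays fixed.
#'
#' @param map_a,map_b numeric maps over the ensemble's parcels.
#' @param ensemble a `null_ensemble`.
#' @param sided sidedness of the permutation p-value (default two-sided).
#' @return A one-row tibble: `estimate` (r), `p_spin`, `null_mean`,
#'   `null_sd`, `n_null`, `sided`.
#' @export
spin_correlation <- function(map_a, map_b, ensemble, sided = "two") {
  if (sd(map_a) == 0 || sd(map_b) == 0) abort("zero-variance map")
  if (length(map_a) != length(map_b)) abort("map lengths differ")
  r <- cor(map_a, map_b)
  nulls <- null_maps(ensemble, map_a)
  null_r <- as.vector(cor(nulls, map_b))
  tibble::tibble(
    estimate = r,
    p_spin = perm_pvalue(r, null_r, sided = sided),
    null_mean = mean(null_r),
    null_sd = sd(null_r),
    n_null = ensemble$n_null,
    sided = sided
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q rejection threshold on the adjusted values (default 0.05).
#' @return A tibble: `p_value`, `p_adjusted`, `rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values))) abort("p-values must be finite")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj, rejected = adj < q)
}
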