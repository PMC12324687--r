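# Spatially autocorrelated scalar fields on the parcel geometry: white
# noise smoothed with a Gaussian kernel of geodesic distance, then
# standardized. These fields carry the spatial autocorrelation that the
# null models must respect, and seed every synthetic map in the package.

smoothing_kernel <- function(distances, lengthscale) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    abort("`distances` must be a square matrix")
  }
  if (all(distances == 0)) abort("degenerate distance matrix: all zeros")
  if (!is.numeric(lengthscale) || lengthscale <= 0) {
    abort("`lengthscale` must be > 0")
  }
  exp(-distances^2 / (2 * lengthscale^2))
}

#' Generate smooth random fields on a spherical parcel geometry
#'
#' Each field is i.i.d. standard Gaussian noise per parcel, smoothed by the
#' kernel `exp(-d^2 / (2 * lengthscale^2))` over geodesic distance `d`, then
#' standardized to mean 0, sample sd 1. Larger lengthscales yield stronger
#' spatial autocorrelation.
#'
#' @param geometry a `sphere_geometry`, or a distance matrix in radians.
#' @param lengthscale kernel lengthscale in radians, in `(0, pi]` typically.
#' @param n number of independent fields.
#' @param seed integer seed; identical seeds give identical fields.
#' @return A parcel x `n` matrix (or a vector when `n = 1`).
#' @export
smooth_field <- function(geometry, lengthscale = 0.4, n = 1, seed = NULL) {
  d <- if (inherits(geometry, "sphere_geometry")) geometry$distances else geometry
  k <- smoothing_kernel(d, lengthscale)
  z <- with_seed(seed, matrix(rnorm(nrow(d) * n), nrow(d), n))
  f <- k %*% z
  f <- apply(f, 2L, function(col) zscore(col, "smooth field"))
  if (n == 1) as.vector(f) else f
}
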