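# Spherical geometry primitives consumed by the null models and the
# synthetic cohort generator. All distances are great-circle distances on
# the unit sphere, in radians; callers rescale if physical units are needed.

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic, well-spaced parcel centroids used as synthetic stand-in
#' geometry for a cortical parcellation projected to a sphere.
#'
#' @param n number of points.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build a spherical parcel geometry
#'
#' Bundles parcel centroid coordinates, a parcel table and the pairwise
#' geodesic distance matrix; every downstream stage (smooth fields, spins,
#' surrogates) consumes this object.
#'
#' @param n_parcels number of parcels; centroids are placed on a Fibonacci
#'   lattice.
#' @param coords optional `n x 3` matrix of unit-vector centroids overriding
#'   the lattice.
#' @param hemisphere optional character vector tagging each parcel `"L"` or
#'   `"R"`; defaults to the sign of the x coordinate.
#' @return An object of class `sphere_geometry`: list with `parcels` (a
#'   tibble: parcel_id, name, hemisphere, x, y, z), `coords`, and `distances`
#'   (parcel x parcel, radians).
#' @export
sphere_geometry <- function(n_parcels = 400, coords = NULL, hemisphere = NULL) {
  if (is.null(coords)) coords <- fibonacci_sphere(n_parcels)
  check_matrix(coords, "coords")
  n_parcels <- nrow(coords)
  if (is.null(hemisphere)) hemisphere <- ifelse(coords[, 1] >= 0, "R", "L")
  dist <- great_circle_distance(coords)
  parcels <- tibble::tibble(
    parcel_id = seq_len(n_parcels),
    name = sprintf("parcel_%03d", seq_len(n_parcels)),
    hemisphere = hemisphere,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  structure(
    list(parcels = parcels, coords = unname(coords), distances = dist),
    class = "sphere_geometry"
  )
}

#' @export
print.sphere_geometry <- function(x, ...) {
  cat(sprintf(
    "<sphere_geometry> %d parcels, max geodesic distance %.3f rad\n",
    nrow(x$parcels), max(x$distances)
  ))
  invisible(x)
}

#' Great-circle distance matrix between unit vectors
#'
#' @param coords `n x 3` matrix; rows must be unit-norm within `1e-6`.
#' @return Symmetric `n x n` matrix of arc lengths in radians, zero diagonal,
#'   values in `[0, pi]`.
#' @export
great_circle_distance <- function(coords) {
  check_matrix(coords, "coords")
  if (ncol(coords) != 3) abort("`coords` must have 3 columns")
  nrm <- sqrt(rowSums(coords^2))
  bad <- which(abs(nrm - 1) > 1e-6)
  if (length(bad)) {
    abort(sprintf(
      "coordinates not unit-norm at row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  g <- tcrossprod(coords)
  d <- acos(pmin(pmax(g, -1), 1))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Centroid vertex of each parcel on a spherical mesh
#'
#' For each parcel: average the member vertex coordinates, renormalize the
#' mean direction to the sphere, and return the member vertex closest (by
#' great-circle distance) to that direction. Ties resolve to the lowest
#' vertex index. Label 0 marks excluded vertices (medial-wall analog).
#'
#' @param vertex_coords `n_vertices x 3` unit vectors.
#' @param labels integer parcel id per vertex; 0 = excluded.
#' @return A tibble with `parcel_id`, `centroid_vertex` (index into
#'   `vertex_coords`), and the centroid direction `x`, `y`, `z`.
#' @export
parcel_centroids <- function(vertex_coords, labels) {
  check_matrix(vertex_coords, "vertex_coords")
  if (length(labels) != nrow(vertex_coords)) {
    abort("`labels` must have one entry per vertex")
  }
  ids <- sort(unique(labels[labels != 0]))
  rows <- lapply(ids, function(id) {
    members <- which(labels == id)
    m <- colMeans(vertex_coords[members, , drop = FALSE])
    nm <- sqrt(sum(m^2))
    if (nm < 1e-9) {
      abort(sprintf("parcel %s has an undefined mean direction (antipodal members)", id))
    }
    m <- m / nm
    # nearest member vertex = max dot product; which.max takes the first
    # (lowest-index) maximum, giving the documented tie rule
    dots <- as.vector(vertex_coords[members, , drop = FALSE] %*% m)
    v <- members[which.max(round(dots, 12))]
    tibble::tibble(
      parcel_id = id, centroid_vertex = v,
      x = m[1], y = m[2], z = m[3]
    )
  })
  dplyr::bind_rows(rows)
}

#' Haar-uniform random 3D rotation
#'
#' QR decomposition of a standard Gaussian matrix with the sign of the
#' R diagonal fixed (so Q is Haar on O(3)), then one column flipped if
#' needed to land in SO(3).
#'
#' @param seed integer seed; the same seed always yields the same matrix.
#' @return A 3 x 3 rotation matrix (orthogonal, determinant +1).
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    m <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

#' Read / write the canonical parcel table
#'
#' The interchange format is a TSV with columns `parcel_id`, `name`,
#' `hemisphere`, `x`, `y`, `z` (unit-sphere centroid coordinates).
#'
#' @param path file path.
#' @return `read_parcel_table()` returns a `sphere_geometry`.
#' @export
read_parcel_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("parcel_id", "name", "hemisphere", "x", "y", "z")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort(paste0("parcel table missing column(s): ", paste(missing, collapse = ", ")))
  }
  coords <- as.matrix(tab[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(coords^2))
  coords <- coords / nrm
  geom <- sphere_geometry(coords = coords, hemisphere = tab$hemisphere)
  geom$parcels$parcel_id <- tab$parcel_id
  geom$parcels$name <- tab$name
  geom
}

#' @rdname read_parcel_table
#' @param geometry a `sphere_geometry`.
#' @export
write_parcel_table <- function(geometry, path) {
  readr::write_tsv(geometry$parcels, path)
  invisible(path)
}
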