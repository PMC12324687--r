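# Synthetic spherical cohort generator. Emulates the statistical structure
# population perfusion analyses assume: positive right-skewed perfusion with
# spatial autocorrelation, a dominant shared spatial component, a sex
# offset, region-dependent age slopes (stronger in "transmodal" cortex),
# block-structured inter-subject covariance ("vascular territories"), and a
# low-rank perfusion-biomarker coupling. Ground truth for every planted
# effect is returned so downstream stages can be validated by recovery.

#' Configuration for the synthetic cohort generator
#'
#' The mean model is multiplicative (log link), so no combination of
#' effects can produce negative perfusion:
#' `mu_iv = exp(log_base + scale * m_v + s * female_i + b_v * (age_i - mean age) + t_i[tau(v)])`
#' with `m` the shared smooth field, `b` the regional age-slope field and
#' `t` per-subject territory factors; the observation is drawn from a
#' generalized gamma around `mu_iv`.
#'
#' @param n_subjects,n_parcels cohort dimensions.
#' @param age_range years; either a length-2 vector or a list of disjoint
#'   ranges (sampled with probability proportional to width) to mimic a
#'   development + aging two-cohort design.
#' @param sex_ratio proportion of female participants.
#' @param log_base baseline log perfusion; `exp(log_base)` is the grand
#'   median in ml/100g/min-like units.
#' @param shared_map_scale sd of the shared spatial component on the log
#'   scale.
#' @param sex_offset additive female offset on the log scale.
#' @param base_slope log-scale perfusion change per year in unimodal cortex.
#' @param transmodal_mult multiplier on `base_slope` in the transmodal cap.
#' @param slope_sd sd of smooth regional jitter added to the slope field
#'   (per year, log scale).
#' @param gg_sigma,gg_nu scale and shape of the generalized-gamma
#'   observation noise.
#' @param n_territories number of longitude-sector territories.
#' @param territory_sd sd of the per-subject, per-territory log-scale factor.
#' @param n_biomarkers,n_coupled,coupling biomarker block: `n_coupled`
#'   measures load on the cohort's age latent with correlation `coupling`;
#'   the rest are independent noise.
#' @param lengthscale smooth-field lengthscale, radians.
#' @param seed master seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 200, n_parcels = 400,
                          age_range = c(8, 80), sex_ratio = 0.5,
                          log_base = log(50), shared_map_scale = 0.3,
                          sex_offset = 0.1, base_slope = -0.005,
                          transmodal_mult = 2, slope_sd = 0.001,
                          gg_sigma = 0.08, gg_nu = 1.5,
                          n_territories = 2, territory_sd = 0.25,
                          n_biomarkers = 28, n_coupled = 10, coupling = 0.8,
                          lengthscale = 0.4, seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, n_parcels = n_parcels, age_range = age_range,
    sex_ratio = sex_ratio, log_base = log_base,
    shared_map_scale = shared_map_scale, sex_offset = sex_offset,
    base_slope = base_slope, transmodal_mult = transmodal_mult,
    slope_sd = slope_sd, gg_sigma = gg_sigma, gg_nu = gg_nu,
    n_territories = n_territories, territory_sd = territory_sd,
    n_biomarkers = n_biomarkers, n_coupled = n_coupled, coupling = coupling,
    lengthscale = lengthscale, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_subjects > 0, cfg$n_parcels > 1,
    cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
    cfg$lengthscale > 0, cfg$lengthscale < pi,
    cfg$n_territories >= 1, cfg$n_coupled <= cfg$n_biomarkers,
    cfg$coupling >= 0, cfg$coupling <= 1
  )
  class(cfg) <- "cohort_config"
  cfg
}

draw_ages <- function(age_range, n) {
  if (!is.list(age_range)) age_range <- list(age_range)
  widths <- vapply(age_range, function(r) diff(range(r)), numeric(1))
  which_range <- sample.int(length(age_range), n, replace = TRUE,
                            prob = widths / sum(widths))
  vapply(seq_len(n), function(i) {
    r <- age_range[[which_range[i]]]
    runif(1, min(r), max(r))
  }, numeric(1))
}

# Longitude-sector territory labels: k equal sectors of atan2(y, x).
territory_labels <- function(coords, k) {
  if (k == 1) return(rep(1L, nrow(coords)))
  lon <- atan2(coords[, 2], coords[, 1]) # [-pi, pi)
  as.integer(cut(lon, breaks = seq(-pi, pi, length.out = k + 1),
                 include.lowest = TRUE, labels = FALSE))
}

#' Simulate a synthetic perfusion cohort
#'
#' @param config a [cohort_config()].
#' @param geometry a [sphere_geometry()]; defaults to a Fibonacci lattice
#'   with `config$n_parcels` parcels.
#' @return A `synthetic_cohort`: list with
#'   \describe{
#'     \item{subject_matrix}{subjects x parcels positive perfusion values}
#'     \item{covariates}{tibble: subject_id, age, sex (male = 1, female = 0)}
#'     \item{biomarkers}{subjects x measures matrix}
#'     \item{truth}{planted ground truth: `shared_map`, `slope_map`,
#'       `network` ("unimodal"/"transmodal"), `territory` labels,
#'       `coupled_biomarkers` index set, and the latent the coupled
#'       biomarkers load on}
#'     \item{geometry}{the geometry used}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config(), geometry = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(geometry)) geometry <- sphere_geometry(config$n_parcels)
  coords <- geometry$coords
  np <- nrow(coords)
  ns <- config$n_subjects

  shared <- smooth_field(geometry, config$lengthscale,
                         seed = derive_seed(config$seed, 1))
  transmodal <- coords[, 3] > 0 # contiguous cap standing in for association cortex
  slope <- config$base_slope *
    (1 + (config$transmodal_mult - 1) * as.numeric(transmodal))
  if (config$slope_sd > 0) {
    slope <- slope + config$slope_sd *
      smooth_field(geometry, config$lengthscale, seed = derive_seed(config$seed, 2))
  }
  terr <- territory_labels(coords, config$n_territories)

  covariates <- with_seed(derive_seed(config$seed, 3), {
    age <- draw_ages(config$age_range, ns)
    n_female <- round(config$sex_ratio * ns)
    sex <- sample(c(rep(0L, n_female), rep(1L, ns - n_female)))
    tibble::tibble(
      subject_id = sprintf("sub_%04d", seq_len(ns)),
      age = age, sex = sex
    )
  })

  tfac <- with_seed(derive_seed(config$seed, 4),
    matrix(rnorm(ns * config$n_territories, sd = config$territory_sd),
           ns, config$n_territories))

  female <- 1 - covariates$sex
  age_c <- covariates$age - mean(covariates$age)
  log_mu <- config$log_base +
    outer(rep(1, ns), config$shared_map_scale * shared) +
    config$sex_offset * outer(female, rep(1, np)) +
    outer(age_c, slope) +
    tfac[, terr, drop = FALSE]
  if (any(!is.finite(log_mu))) {
    abort("configuration yields non-finite mean perfusion; check effect sizes")
  }
  mu <- exp(log_mu)

  y <- with_seed(derive_seed(config$seed, 5),
    matrix(rgg(length(mu), mu = as.vector(mu),
               sigma = config$gg_sigma, nu = config$gg_nu), ns, np))
  dimnames(y) <- list(covariates$subject_id, geometry$parcels$name)

  # biomarkers: coupled subset loads on the (negated) age latent, so
  # "healthier biomarker profile <-> younger <-> higher perfusion"
  latent <- -zscore(covariates$age, "age")
  biom <- with_seed(derive_seed(config$seed, 6), {
    b <- matrix(rnorm(ns * config$n_biomarkers), ns, config$n_biomarkers)
    if (config$n_coupled > 0) {
      idx <- seq_len(config$n_coupled)
      b[, idx] <- config$coupling * latent +
        sqrt(1 - config$coupling^2) * b[, idx]
    }
    b
  })
  colnames(biom) <- sprintf("biomarker_%02d", seq_len(config$n_biomarkers))
  rownames(biom) <- covariates$subject_id

  structure(list(
    subject_matrix = y,
    covariates = covariates,
    biomarkers = biom,
    truth = list(
      shared_map = shared,
      slope_map = slope,
      network = ifelse(transmodal, "transmodal", "unimodal"),
      territory = terr,
      coupled_biomarkers = seq_len(config$n_coupled),
      latent = latent,
      mu = mu
    ),
    geometry = geometry,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d parcels, ages %.1f-%.1f, %d biomarkers\n",
    nrow(x$subject_matrix), ncol(x$subject_matrix),
    min(x$covariates$age), max(x$covariates$age), ncol(x$biomarkers)
  ))
  invisible(x)
}

#' Simulate annotation maps with a planted enriched category
#'
#' Emulates a transcriptomic annotation resource: `n_annotations` maps over
#' the parcels, a named category structure, and one planted category whose
#' members mix the target map (weight `alpha`) with independent smooth
#' fields (weight `sqrt(1 - alpha^2)`), so each member correlates with the
#' target at about `alpha`. Optional per-donor replicates support
#' differential-stability filtering.
#'
#' @param geometry a `sphere_geometry`.
#' @param target parcel map the planted category tracks.
#' @param n_annotations total number of annotation maps.
#' @param planted_size members in the planted category.
#' @param alpha coupling of planted members to the target, in `[0, 1]`.
#' @param decoy_size members per decoy category (remaining maps are split
#'   into decoy categories of this size).
#' @param n_donors,donor_sd if `n_donors >= 2`, per-donor replicate maps are
#'   `map + N(0, donor_sd)` noise, enabling DS computation.
#' @param lengthscale smooth-field lengthscale for annotation maps.
#' @param seed integer seed.
#' @return An `annotation_set`: list with `maps` (annotation x parcel
#'   matrix), `categories` (named list of member names), `planted` (the
#'   planted category id) and optionally `donor_maps` (list of per-donor
#'   annotation x parcel matrices).
#' @export
simulate_annotations <- function(geometry, target, n_annotations = 540,
                                 planted_size = 40, alpha = 0.8,
                                 decoy_size = 10, n_donors = 0,
                                 donor_sd = 0.3, lengthscale = 0.4,
                                 seed = 1L) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1]")
  if (planted_size < 2) abort("`planted_size` must be at least 2")
  if (planted_size > n_annotations) abort("planted category larger than annotation pool")
  np <- nrow(geometry$parcels)
  if (length(target) != np) abort("`target` must have one value per parcel")
  tz <- zscore(target, "target map")

  fields <- smooth_field(geometry, lengthscale, n = n_annotations,
                         seed = derive_seed(seed, 11))
  maps <- t(fields) # annotation x parcel
  idx <- seq_len(planted_size)
  maps[idx, ] <- alpha * matrix(tz, planted_size, np, byrow = TRUE) +
    sqrt(1 - alpha^2) * maps[idx, , drop = FALSE]
  rownames(maps) <- sprintf("ann_%04d", seq_len(n_annotations))
  colnames(maps) <- geometry$parcels$name

  planted_id <- "planted_category"
  decoys <- setdiff(seq_len(n_annotations), idx)
  n_decoy <- length(decoys) %/% decoy_size
  categories <- c(
    stats::setNames(list(rownames(maps)[idx]), planted_id),
    stats::setNames(
      lapply(seq_len(n_decoy), function(k) {
        rownames(maps)[decoys[((k - 1) * decoy_size + 1):(k * decoy_size)]]
      }),
      sprintf("decoy_%03d", seq_len(n_decoy))
    )
  )

  donor_maps <- NULL
  if (n_donors >= 2) {
    donor_maps <- with_seed(derive_seed(seed, 12), {
      lapply(seq_len(n_donors), function(d) {
        maps + matrix(rnorm(length(maps), sd = donor_sd),
                      nrow(maps), ncol(maps), dimnames = dimnames(maps))
      })
    })
    names(donor_maps) <- sprintf("donor_%d", seq_len(n_donors))
  }

  structure(list(
    maps = maps, categories = categories, planted = planted_id,
    donor_maps = donor_maps
  ), class = "annotation_set")
}

#' Write a synthetic cohort to plain-text interchange files
#'
#' Subject matrix and covariates as TSV, ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "subject_matrix.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    biomarkers = file.path(dir, "biomarkers.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(tibble::as_tibble(cohort$subject_matrix, rownames = "subject_id"),
                   paths["matrix"])
  readr::write_tsv(cohort$covariates, paths["covariates"])
  readr::write_tsv(tibble::as_tibble(cohort$biomarkers, rownames = "subject_id"),
                   paths["biomarkers"])
  jsonlite::write_json(cohort$truth[c("shared_map", "slope_map", "network",
                                      "territory", "coupled_biomarkers")],
                       paths["truth"], digits = NA)
  invisible(paths)
}
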