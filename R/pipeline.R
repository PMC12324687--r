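# One-command end-to-end run on a synthetic cohort, plus parcel-map I/O in
# the package's interchange format.

#' Read a parcel-keyed map from TSV
#'
#' Expects columns `parcel_id` and `value`; the result is ordered to match
#' the geometry's parcel order. Duplicate ids, parcels missing relative to
#' the geometry, and non-finite values are errors (no silent imputation).
#'
#' @param path TSV file path.
#' @param geometry a `sphere_geometry` defining the parcel order.
#' @return Named numeric vector over the geometry's parcels.
#' @export
load_parcel_map <- function(path, geometry) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("parcel_id", "value") %in% names(tab))) {
    abort("parcel map must have columns `parcel_id` and `value`")
  }
  if (anyDuplicated(tab$parcel_id)) {
    abort(sprintf("duplicate parcel_id(s): %s",
                  paste(unique(tab$parcel_id[duplicated(tab$parcel_id)]), collapse = ", ")))
  }
  want <- geometry$parcels$parcel_id
  missing <- setdiff(want, tab$parcel_id)
  if (length(missing)) {
    abort(sprintf("parcel map missing %d geometry parcel(s): %s",
                  length(missing), paste(missing, collapse = ", ")))
  }
  vals <- tab$value[match(want, tab$parcel_id)]
  if (any(!is.finite(vals))) abort("parcel map contains non-finite values")
  stats::setNames(vals, geometry$parcels$name)
}

#' Write a parcel-keyed map to TSV
#'
#' @param map numeric vector over parcels.
#' @param geometry a `sphere_geometry`.
#' @param path output path.
#' @export
write_parcel_map <- function(map, geometry, path) {
  readr::write_tsv(
    tibble::tibble(parcel_id = geometry$parcels$parcel_id, value = map),
    path
  )
  invisible(path)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort, then runs the enabled stages in dependency order:
#' score maps (PCA of subject-standardized perfusion), per-parcel GLM age
#' and sex effects with a unimodal/transmodal contrast, spatial null
#' ensembles, category enrichment on simulated annotations, behavioral PLS
#' with permutation/bootstrap/cross-validation, generalized-gamma
#' trajectories of whole-brain perfusion, and covariance gradients.
#'
#' @param config a [cohort_config()].
#' @param stages character vector of stages to run (any of `"scoremaps"`,
#'   `"glm"`, `"enrichment"`, `"pls"`, `"trajectories"`, `"territories"`;
#'   simulation and the null ensemble always run).
#' @param n_null,n_perm,n_boot,n_splits resampling sizes.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/JSON.
#' @return A `run_manifest`: list with `results` (per-stage objects),
#'   `manifest` (tibble of stage, parameters, output hash) and the resolved
#'   config.
#' @export
run_pipeline <- function(config = cohort_config(),
                         stages = c("scoremaps", "glm", "enrichment", "pls",
                                    "trajectories", "territories"),
                         n_null = 1000, n_perm = 1000, n_boot = 1000,
                         n_splits = 1000, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  results <- list()
  rows <- list()
  note <- function(stage, params, object) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      stage = stage,
      parameters = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
      hash = hash_object(object)
    )
  }

  cohort <- simulate_cohort(config)
  results$cohort <- cohort
  note("simulate", config[setdiff(names(config), "")], cohort$subject_matrix)
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort"))

  ensemble <- vasa_assignments(cohort$geometry, n_null = n_null,
                               seed = derive_seed(config$seed, 101))
  results$ensemble <- ensemble
  note("nulls", list(kind = "vasa", n_null = n_null), ensemble$assignments)

  zmat <- standardize_subjects(cohort$subject_matrix)

  if ("scoremaps" %in% stages) {
    sm <- pca_score_map(zmat)
    results$score_map <- sm
    note("scoremaps", list(center_columns = FALSE), sm$score_map)
    if (!is.null(out_dir)) {
      write_parcel_map(sm$score_map, cohort$geometry,
                       file.path(out_dir, "score_map.tsv"))
    }
  }

  if ("glm" %in% stages) {
    glm_tab <- glm_effect_maps(log(cohort$subject_matrix), cohort$covariates,
                               terms = c("age", "sex"))
    contrast <- network_contrast(coefficient_map(glm_tab, "age"),
                                 cohort$truth$network == "transmodal",
                                 ensemble)
    results$glm <- glm_tab
    results$network_contrast <- contrast
    note("glm", list(terms = c("age", "sex")), glm_tab)
    if (!is.null(out_dir)) {
      readr::write_tsv(glm_tab, file.path(out_dir, "glm_effect_maps.tsv"))
    }
  }

  if ("enrichment" %in% stages) {
    target <- if (!is.null(results$score_map)) {
      results$score_map$score_map
    } else {
      zscore(colMeans(zmat), "mean map")
    }
    ann <- simulate_annotations(cohort$geometry, target,
                                seed = derive_seed(config$seed, 102))
    gcea <- run_gcea(target, ann, ensemble, min_size = 5)
    results$enrichment <- gcea
    note("enrichment", list(min_size = 5, n_null = n_null), gcea)
    if (!is.null(out_dir)) {
      readr::write_tsv(gcea, file.path(out_dir, "enrichment.tsv"))
    }
  }

  if ("pls" %in% stages) {
    model <- pls_fit(cohort$subject_matrix, cohort$biomarkers)
    perm <- pls_permutation(model, n_perm = n_perm,
                            seed = derive_seed(config$seed, 103))
    boot <- pls_bootstrap(model, n_boot = n_boot,
                          seed = derive_seed(config$seed, 104))
    cv <- pls_crossval(cohort$subject_matrix, cohort$biomarkers,
                       n_splits = n_splits, n_perm = n_perm,
                       seed = derive_seed(config$seed, 105))
    results$pls <- list(model = model, permutation = perm,
                        bootstrap = boot, crossval = cv)
    note("pls", list(n_perm = n_perm, n_boot = n_boot), perm)
    if (!is.null(out_dir)) {
      readr::write_tsv(boot$biomarkers, file.path(out_dir, "pls_bootstrap_ratios.tsv"))
    }
  }

  if ("trajectories" %in% stages) {
    whole_brain <- rowMeans(cohort$subject_matrix)
    fits <- lapply(split(seq_len(nrow(zmat)), cohort$covariates$sex), function(idx) {
      fit_gg_fp(cohort$covariates$age[idx], whole_brain[idx])
    })
    names(fits) <- ifelse(names(fits) == "1", "male", "female")
    results$trajectories <- fits
    note("trajectories", list(stratify = "sex"), lapply(fits, glance))
  }

  if ("territories" %in% stages) {
    cg <- perfusion_covariance(cohort$subject_matrix)
    # sparsity 0.5 keeps exactly the within-block half of each row for the
    # default two-territory design; see the methods vignette
    gr <- diffusion_gradients(cg, sparsity = 0.5)
    results$territories <- gr
    note("territories", list(n_components = 5), gr$gradients)
    if (!is.null(out_dir)) {
      readr::write_tsv(tidy(gr), file.path(out_dir, "gradients.tsv"))
    }
  }

  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  structure(list(results = results, manifest = manifest, config = config),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(x$manifest)
  invisible(x)
}
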