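# Ensemble-null category enrichment: does a named set of annotation maps
# (e.g., the genes of a GO category) correlate with a target brain map more
# than with spatially autocorrelated null versions of that target? The null
# is applied to the target phenotype, never to the annotation maps.

fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip)) # data-first keeps matrix dims
}

#' Differential stability of annotation maps across donors
#'
#' DS of an annotation is the mean pairwise Pearson correlation of its map
#' across donor pairs — a reproducibility filter. Donor pairs in which
#' either map has zero variance are skipped; an annotation with no usable
#' pair is an error.
#'
#' @param donor_maps list (length >= 2) of annotation x parcel matrices,
#'   one per donor, with identical row names.
#' @return A tibble: `annotation`, `ds`.
#' @export
differential_stability <- function(donor_maps) {
  if (length(donor_maps) < 2) abort("need at least 2 donors")
  n_ann <- nrow(donor_maps[[1]])
  pairs <- combn(length(donor_maps), 2)
  ds <- vapply(seq_len(n_ann), function(a) {
    rs <- apply(pairs, 2L, function(pr) {
      x <- donor_maps[[pr[1]]][a, ]
      y <- donor_maps[[pr[2]]][a, ]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    })
    rs <- rs[!is.na(rs)]
    if (!length(rs)) {
      nm <- rownames(donor_maps[[1]])[a]
      abort(sprintf("DS undefined for annotation %s: all donor pairs degenerate",
                    if (is.null(nm)) a else nm))
    }
    mean(rs)
  }, numeric(1))
  tibble::tibble(
    annotation = rownames(donor_maps[[1]]) %||% as.character(seq_len(n_ann)),
    ds = ds
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Category score: mean Fisher-z correlation with a target map
#'
#' @param target numeric map over parcels.
#' @param member_maps members x parcels matrix of annotation maps.
#' @return Scalar score: mean over members of `atanh(r)` with `r` clipped
#'   to `|r| <= 1 - 1e-7` to keep the score finite.
#' @export
category_score <- function(target, member_maps) {
  if (is.vector(member_maps)) member_maps <- matrix(member_maps, nrow = 1)
  if (!nrow(member_maps)) abort("category must have at least one member")
  svar <- apply(member_maps, 1L, sd)
  if (any(svar == 0)) {
    nm <- rownames(member_maps)[which(svar == 0)[1]] %||% which(svar == 0)[1]
    abort(sprintf("zero-variance member map: %s", nm))
  }
  r <- as.vector(cor(t(member_maps), target))
  mean(fisher_z(r))
}

#' Gene category enrichment analysis with an ensemble null
#'
#' For each retained category, the observed score is the mean Fisher-z
#' Pearson correlation of its member maps with the target; null scores
#' recompute the same statistic with the target replaced by each null map
#' from the ensemble. Positive-sided inclusive permutation p-values are
#' FDR-corrected (Benjamini-Hochberg) across categories.
#'
#' @param target numeric map over parcels.
#' @param annotations an `annotation_set` (see [simulate_annotations()]), or
#'   a list with `maps` (annotation x parcel matrix) and `categories`
#'   (named list of member-name vectors).
#' @param ensemble a `null_ensemble` over the same parcels.
#' @param min_size categories must have strictly more than `min_size`
#'   members after filtering (default 30, the conventional GO cutoff; lower
#'   it for small synthetic category structures).
#' @param ds optional tibble from [differential_stability()]; annotations
#'   with `ds < ds_threshold` are dropped before scoring.
#' @param ds_threshold differential-stability cutoff (default 0.1).
#' @param q FDR threshold for the `rejected` column.
#' @return An `enrichment_table` tibble sorted by score (descending, stable):
#'   `category`, `n_members`, `score`, `null_mean`, `null_sd`, `z_score`
#'   (null-standardized score), `p_value`, `p_adjusted`, `rejected`.
#' @export
run_gcea <- function(target, annotations, ensemble, min_size = 30,
                     ds = NULL, ds_threshold = 0.1, q = 0.05) {
  maps <- annotations$maps
  categories <- annotations$categories
  if (!is.null(ds)) {
    keep <- ds$annotation[ds$ds >= ds_threshold]
    maps <- maps[rownames(maps) %in% keep, , drop = FALSE]
  }
  categories <- lapply(categories, intersect, y = rownames(maps))
  categories <- categories[vapply(categories, length, integer(1)) > min_size]
  if (!length(categories)) abort("no categories retained after filtering")

  used <- unique(unlist(categories))
  maps <- maps[used, , drop = FALSE]
  svar <- apply(maps, 1L, sd)
  if (any(svar == 0)) {
    abort(sprintf("zero-variance member map: %s",
                  rownames(maps)[which(svar == 0)[1]]))
  }

  targets <- cbind(observed = target, null_maps(ensemble, target))
  z <- fisher_z(cor(t(maps), targets)) # annotation x (1 + n_null)
  member_idx <- lapply(categories, match, table = rownames(maps))
  ind <- matrix(0, length(categories), nrow(maps))
  for (i in seq_along(member_idx)) {
    ind[i, member_idx[[i]]] <- 1 / length(member_idx[[i]])
  }
  scores <- ind %*% z # category x (1 + n_null)
  obs <- scores[, 1]
  nulls <- scores[, -1, drop = FALSE]
  pvals <- (1 + rowSums(nulls >= obs)) / (1 + ncol(nulls))
  fdr <- bh_fdr(pvals, q = q)
  null_sd <- apply(nulls, 1L, sd)
  out <- tibble::tibble(
    category = names(categories),
    n_members = lengths(categories),
    score = obs,
    null_mean = rowMeans(nulls),
    null_sd = null_sd,
    z_score = (obs - rowMeans(nulls)) / null_sd,
    p_value = pvals,
    p_adjusted = fdr$p_adjusted,
    rejected = fdr$rejected
  )
  out <- out[order(-out$score), ]
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Read category definitions from TSV or GMT-style files
#'
#' Two formats: a two-column TSV (`category_id`, `member`), or GMT lines
#' (`category<TAB>description<TAB>member1<TAB>member2...`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return Named list of member-name character vectors.
#' @export
read_categories <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("category_id", "member") %in% names(tab))) {
      abort("category TSV must have columns `category_id` and `member`")
    }
    return(split(tab$member, tab$category_id))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) p[-(1:2)]),
    vapply(parts, `[[`, character(1), 1)
  )
}
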