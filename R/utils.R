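# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a counter
#'
#' Heavy resampling loops (null ensembles, bootstraps, cross-validation
#' splits) draw one child seed per iteration from a master seed, so results
#' are identical whether iterations run in order or not.
#'
#' @param master integer master seed.
#' @param counter non-negative integer iteration index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime (Lehmer modulus)
  x <- (abs(as.double(master)) %% m + 1)
  x <- (x * 48271) %% m
  x <- (x + (as.double(counter) %% m) * 16807) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1) + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# z-score a vector with sample sd (divisor n - 1); errors on zero variance.
zscore <- function(x, what = "vector") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot z-score %s: zero or non-finite variance", what))
  }
  (x - mean(x)) / s
}

# Column-wise z-scoring of a matrix (sample sd).
zscore_cols <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    nm <- if (!is.null(colnames(x))) colnames(x)[bad] else as.character(bad)
    abort(paste0("constant column(s): ", paste(nm, collapse = ", ")))
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
}

# Row-wise z-scoring (sample sd), used for subject-level standardization.
zscore_rows <- function(x, row_label = "row") {
  s <- apply(x, 1L, sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    nm <- if (!is.null(rownames(x))) rownames(x)[bad] else as.character(bad)
    abort(paste0("constant ", row_label, "(s): ", paste(nm, collapse = ", ")))
  }
  (x - rowMeans(x)) / s
}

check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values", name))
  }
  invisible(x)
}
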