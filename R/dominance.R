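# Dominance analysis: decomposes a linear model's R^2 into per-predictor
# contributions by averaging each predictor's incremental R^2 over all
# subsets of the remaining predictors (total dominance). Contributions sum
# exactly to the full-model R^2.

subset_r2 <- function(x, y, mask_cols) {
  if (!length(mask_cols)) return(0)
  fit <- lm.fit(cbind(1, x[, mask_cols, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Dominance analysis of a linear regression
#'
#' For each predictor, the total-dominance contribution is the average —
#' over subset sizes, then over all subsets of that size not containing the
#' predictor — of the increase in R^2 from adding it. Exact enumeration of
#' all `2^p` subsets; refuses `p > 20`.
#'
#' @param x subjects x predictors matrix (no intercept column).
#' @param y response vector.
#' @return A `dominance_result` tibble: `predictor`, `contribution`,
#'   `percent` (of total R^2), with the full-model R^2 in attribute
#'   `total_r2` and reported by `glance()`.
#' @export
dominance_analysis <- function(x, y) {
  check_matrix(x, "x")
  p <- ncol(x)
  if (p > 20) abort("more than 20 predictors: exact enumeration refused; select a subset")
  if (qr(cbind(1, x))$rank < p + 1) abort("rank-deficient predictor matrix")
  n_sub <- 2^p
  r2 <- numeric(n_sub) # r2[mask + 1]
  masks <- 0:(n_sub - 1)
  member <- function(mask, j) bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L
  for (m in masks) {
    cols <- which(vapply(seq_len(p), function(j) member(m, j), logical(1)))
    r2[m + 1] <- subset_r2(x, y, cols)
  }
  # acc[j, k+1]: running mean of increments for predictor j over subsets of size k
  inc_sum <- matrix(0, p, p)
  inc_n <- matrix(0, p, p)
  for (m in masks) {
    size <- sum(vapply(seq_len(p), function(j) member(m, j), logical(1)))
    for (j in seq_len(p)) {
      if (!member(m, j)) {
        gain <- r2[bitwOr(m, bitwShiftL(1L, j - 1L)) + 1] - r2[m + 1]
        inc_sum[j, size + 1] <- inc_sum[j, size + 1] + gain
        inc_n[j, size + 1] <- inc_n[j, size + 1] + 1
      }
    }
  }
  # each predictor sees subset sizes 0..p-1; average within size, then across
  contrib <- vapply(seq_len(p), function(j) {
    mean((inc_sum[j, ] / pmax(inc_n[j, ], 1))[inc_n[j, ] > 0])
  }, numeric(1))
  total <- r2[n_sub]
  out <- tibble::tibble(
    predictor = colnames(x) %||% sprintf("x%d", seq_len(p)),
    contribution = contrib,
    percent = 100 * contrib / total
  )
  attr(out, "total_r2") <- total
  class(out) <- c("dominance_result", class(out))
  out
}

#' @export
glance.dominance_result <- function(x, ...) {
  tibble::tibble(total_r2 = attr(x, "total_r2"), n_predictors = nrow(x))
}
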