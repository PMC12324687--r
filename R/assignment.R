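# Minimum-cost assignment (Jonker-Volgenant shortest augmenting path,
# O(n^3)). Backs the optional `method = "optimal"` matching in
# vasa_assignments(); the default matching there is the documented greedy
# rule.

#' Solve the minimum-cost assignment problem
#'
#' @param cost square cost matrix (rows = originals, columns = candidates).
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost)) {
    abort("`cost` must be a square matrix")
  }
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1) # index j + 1; j = 0 is the virtual column
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      js <- which(!used[-1])
      cur <- cost[i0, js] - u[i0] - v[js + 1]
      upd <- cur < minv[js + 1]
      if (any(upd)) {
        minv[js[upd] + 1] <- cur[upd]
        way[js[upd] + 1] <- j0
      }
      j1 <- js[which.min(minv[js + 1])]
      delta <- minv[j1 + 1]
      uj <- which(used)
      rows <- p[uj]
      u[rows] <- u[rows] + delta
      v[uj] <- v[uj] - delta
      minv[-uj] <- minv[-uj] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  out[p[-1]] <- seq_len(n)
  out
}
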