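# Normative trajectories: generalized-gamma location-scale-shape model
# with fractional-polynomial age predictors for mu and sigma (log links)
# and a constant shape nu. The best power combination is chosen by
# exhaustive search under a generalized AIC.

fp_powerset <- function(power_set) {
  singles <- lapply(power_set, function(p) p)
  pairs <- if (length(power_set) >= 2) {
    apply(combn(power_set, 2), 2, identity, simplify = FALSE)
  } else list()
  repeated <- lapply(power_set, function(p) c(p, p))
  c(singles, pairs, repeated)
}

#' Fractional-polynomial design matrix
#'
#' One column per power: power 0 maps to `log(x)`; a repeated power `p`
#' contributes `x^p` and `x^p * log(x)` (so `(0, 0)` gives `log(x)` and
#' `log(x)^2`). The intercept column comes first.
#'
#' @param x strictly positive predictor values.
#' @param powers numeric vector of 1-2 powers from the fractional-
#'   polynomial set; `NULL` or empty gives an intercept-only design.
#' @return Design matrix with named columns.
#' @export
fp_design <- function(x, powers = NULL) {
  if (any(x <= 0)) abort("fractional polynomials need strictly positive x")
  out <- matrix(1, length(x), 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(powers) || !length(powers)) return(out)
  if (length(powers) > 2) abort("at most two fractional-polynomial terms")
  base_term <- function(p) if (p == 0) log(x) else x^p
  cols <- list()
  nm <- character(0)
  for (i in seq_along(powers)) {
    p <- powers[i]
    if (i == 2 && powers[1] == p) {
      cols[[i]] <- base_term(p) * log(x)
      nm[i] <- sprintf("fp(%g)*log", p)
    } else {
      cols[[i]] <- base_term(p)
      nm[i] <- sprintf("fp(%g)", p)
    }
  }
  cbind(out, matrix(unlist(cols), length(x), length(cols),
                    dimnames = list(NULL, nm)))
}

gg_nll <- function(par, y, x_mu, x_sigma) {
  p_mu <- ncol(x_mu)
  p_sig <- ncol(x_sigma)
  bmu <- par[seq_len(p_mu)]
  bsig <- par[p_mu + seq_len(p_sig)]
  nu <- par[p_mu + p_sig + 1]
  if (!all(is.finite(par)) || abs(nu) < 1e-3 || abs(nu) > 20) return(1e10)
  eta_mu <- as.vector(x_mu %*% bmu)
  eta_sig <- as.vector(x_sigma %*% bsig)
  if (any(eta_mu > 50) || any(eta_sig > 10) || any(eta_sig < -10)) return(1e10)
  mu <- exp(eta_mu)
  sigma <- exp(eta_sig)
  ll <- tryCatch(sum(dgg(y, mu = mu, sigma = sigma, nu = nu, log = TRUE)),
                 error = function(e) -Inf)
  if (!is.finite(ll)) return(1e10)
  -ll
}

fit_gg_candidate <- function(y, x_mu, x_sigma, n_restarts = 3, seed = 7L) {
  logy <- log(y)
  bmu0 <- qr.coef(qr(x_mu), logy)
  resid <- logy - as.vector(x_mu %*% bmu0)
  bsig0 <- c(log(max(sd(resid), 1e-3)), rep(0, ncol(x_sigma) - 1))
  start <- c(bmu0, bsig0, 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    st <- if (r == 1) start else {
      with_seed(derive_seed(seed, r), start + rnorm(length(start), sd = 0.2))
    }
    fit <- tryCatch(
      optim(st, gg_nll, y = y, x_mu = x_mu, x_sigma = x_sigma,
            method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit a generalized-gamma fractional-polynomial trajectory
#'
#' Exhaustive search over fractional-polynomial power combinations (all
#' one-term models, all distinct pairs and all repeated pairs from the
#' power set) for the location predictor, with a scale intercept only;
#' then, holding the winning location powers, the same search for the
#' scale predictor. Each candidate is fitted by numerical maximum
#' likelihood (log links for mu and sigma, identity for nu) and the winner
#' minimizes `GAIC = -2 loglik + k * n_params`.
#'
#' @param age strictly positive explanatory variable (years).
#' @param y strictly positive responses.
#' @param power_set candidate powers (default the conventional
#'   `-2, -1, -0.5, 0, 0.5, 1, 2, 3`).
#' @param k GAIC penalty per parameter (default 2, i.e. AIC).
#' @param joint if `TRUE`, search mu and sigma powers jointly (slower).
#' @param n_restarts random optimizer restarts per candidate.
#' @return A `trajectory_fit`: selected powers, coefficient vectors on the
#'   log-link scale, `nu`, `loglik`, `gaic`, and the predictor shift/scale
#'   constants.
#' @export
fit_gg_fp <- function(age, y, power_set = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                      k = 2, joint = FALSE, n_restarts = 3) {
  if (length(age) != length(y)) abort("`age` and `y` lengths differ")
  if (length(y) < 30) abort("need at least 30 observations")
  if (any(y <= 0)) abort("responses must be strictly positive")
  shift <- if (any(age <= 0)) 1e-3 - min(age) else 0
  xs <- (age + shift) / 10 # decades, for conditioning
  cands <- fp_powerset(power_set)

  score <- function(pw_mu, pw_sig) {
    x_mu <- fp_design(xs, pw_mu)
    x_sig <- fp_design(xs, pw_sig)
    fit <- fit_gg_candidate(y, x_mu, x_sig, n_restarts = n_restarts)
    if (is.null(fit)) return(NULL)
    npar <- ncol(x_mu) + ncol(x_sig) + 1
    list(fit = fit, gaic = 2 * fit$value + k * npar,
         pw_mu = pw_mu, pw_sig = pw_sig,
         x_mu = x_mu, x_sig = x_sig)
  }

  best <- NULL
  if (joint) {
    sig_cands <- c(list(NULL), cands)
    for (pm in cands) for (ps in sig_cands) {
      res <- score(pm, ps)
      if (!is.null(res) && (is.null(best) || res$gaic < best$gaic)) best <- res
    }
  } else {
    for (pm in cands) {
      res <- score(pm, NULL)
      if (!is.null(res) && (is.null(best) || res$gaic < best$gaic)) best <- res
    }
    if (is.null(best)) abort("optimizer failed to converge on every location candidate")
    pw_mu <- best$pw_mu
    for (ps in cands) {
      res <- score(pw_mu, ps)
      if (!is.null(res) && res$gaic < best$gaic) best <- res
    }
  }
  if (is.null(best)) abort("optimizer failed to converge on every candidate")

  p_mu <- ncol(best$x_mu)
  p_sig <- ncol(best$x_sig)
  par <- best$fit$par
  structure(list(
    powers_mu = best$pw_mu,
    powers_sigma = best$pw_sig,
    beta_mu = stats::setNames(par[seq_len(p_mu)], colnames(best$x_mu)),
    beta_sigma = stats::setNames(par[p_mu + seq_len(p_sig)], colnames(best$x_sig)),
    nu = par[p_mu + p_sig + 1],
    loglik = -best$fit$value,
    gaic = best$gaic,
    gaic_k = k,
    shift = shift,
    scale = 10,
    age_range = range(age),
    n = length(y)
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> mu powers (%s), sigma powers (%s), nu = %.3f, GAIC = %.1f\n",
    paste(x$powers_mu, collapse = ", "),
    if (length(x$powers_sigma)) paste(x$powers_sigma, collapse = ", ") else "intercept",
    x$nu, x$gaic
  ))
  invisible(x)
}

#' Evaluate the fitted distribution parameters over ages
#'
#' @param fit a `trajectory_fit`.
#' @param age ages at which to evaluate.
#' @return A tibble: `age`, `mu`, `sigma`, `nu`.
#' @export
predict_gg_params <- function(fit, age) {
  xs <- (age + fit$shift) / fit$scale
  mu <- exp(as.vector(fp_design(xs, fit$powers_mu) %*% fit$beta_mu))
  sigma <- exp(as.vector(fp_design(xs, fit$powers_sigma) %*% fit$beta_sigma))
  tibble::tibble(age = age, mu = mu, sigma = sigma, nu = fit$nu)
}

#' Normative centile curves from a fitted trajectory
#'
#' @param fit a `trajectory_fit`.
#' @param age_grid ages at which to evaluate the curves.
#' @param centiles probabilities in (0, 1) (default 5th, 50th, 95th).
#' @return A tibble: `age`, `centile`, `value`.
#' @export
centile_curves <- function(fit, age_grid, centiles = c(0.05, 0.5, 0.95)) {
  params <- predict_gg_params(fit, age_grid)
  purrr::map_dfr(centiles, function(p) {
    tibble::tibble(
      age = age_grid,
      centile = p,
      value = qgg(p, mu = params$mu, sigma = params$sigma, nu = params$nu)
    )
  })
}

#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c(rep("mu", length(x$beta_mu)),
                  rep("sigma", length(x$beta_sigma)), "nu"),
    term = c(names(x$beta_mu), names(x$beta_sigma), "nu"),
    estimate = c(x$beta_mu, x$beta_sigma, x$nu)
  )
}

#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    loglik = x$loglik,
    gaic = x$gaic,
    nu = x$nu,
    powers_mu = paste(x$powers_mu, collapse = ","),
    powers_sigma = if (length(x$powers_sigma)) {
      paste(x$powers_sigma, collapse = ",")
    } else "intercept"
  )
}
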