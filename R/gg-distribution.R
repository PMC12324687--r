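# Generalized gamma distribution in the Stacy location-scale-shape
# parameterization (mu > 0, sigma > 0, nu != 0) used by GAMLSS-style
# normative models. With theta = 1/(sigma^2 nu^2) and z = (y/mu)^nu,
# theta * z is Gamma(theta, 1); nu = 1 recovers a gamma law with shape
# theta and mean mu.

check_gg_params <- function(mu, sigma, nu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) abort("`mu` must be finite and > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("`sigma` must be finite and > 0")
  if (any(!is.finite(nu)) || any(nu == 0)) {
    abort("`nu` must be finite and nonzero (the lognormal limit nu = 0 is not parameterized)")
  }
  invisible(NULL)
}

#' Generalized gamma density, distribution, quantile and random generation
#'
#' @param y,q vector of positive observations / quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu location parameter (> 0); the distribution median scales with it.
#' @param sigma scale parameter (> 0).
#' @param nu shape parameter (nonzero real); `nu = 1` gives a gamma
#'   distribution with shape `1/sigma^2` and mean `mu`.
#' @param log,log.p,lower.tail usual conventions.
#' @return `dgg()` the (log-)density, `pgg()` the CDF, `qgg()` quantiles,
#'   `rgg()` random draws. Parameters recycle against the data argument.
#' @export
dgg <- function(y, mu = 1, sigma = 0.5, nu = 1, log = FALSE) {
  if (any(!is.finite(y)) || any(y <= 0)) abort("`y` must be finite and > 0")
  check_gg_params(mu, sigma, nu)
  theta <- 1 / (sigma^2 * nu^2)
  logy <- base::log(y)
  logf <- base::log(abs(nu)) + theta * base::log(theta) +
    theta * nu * (logy - base::log(mu)) -
    theta * (y / mu)^nu - lgamma(theta) - logy
  if (log) logf else exp(logf)
}

#' @rdname dgg
#' @export
pgg <- function(q, mu = 1, sigma = 0.5, nu = 1, lower.tail = TRUE, log.p = FALSE) {
  if (any(!is.finite(q)) || any(q <= 0)) abort("`q` must be finite and > 0")
  check_gg_params(mu, sigma, nu)
  theta <- 1 / (sigma^2 * nu^2)
  z <- (q / mu)^nu
  # for nu < 0, z is decreasing in q, so the gamma CDF is reflected
  p <- ifelse(rep_len(nu, length(z)) > 0,
    pgamma(theta * z, shape = theta),
    pgamma(theta * z, shape = theta, lower.tail = FALSE)
  )
  if (!lower.tail) p <- 1 - p
  if (log.p) base::log(p) else p
}

#' @rdname dgg
#' @export
qgg <- function(p, mu = 1, sigma = 0.5, nu = 1) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1)")
  }
  check_gg_params(mu, sigma, nu)
  k <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, k); mu <- rep_len(mu, k)
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  theta <- 1 / (sigma^2 * nu^2)
  pp <- ifelse(nu > 0, p, 1 - p)
  g <- qgamma(pp, shape = theta)
  mu * (g / theta)^(1 / nu)
}

#' @rdname dgg
#' @param seed optional integer seed for `rgg()`.
#' @export
rgg <- function(n, mu = 1, sigma = 0.5, nu = 1, seed = NULL) {
  check_gg_params(mu, sigma, nu)
  with_seed(seed, {
    theta <- 1 / (sigma^2 * nu^2)
    g <- rgamma(n, shape = theta)
    rep_len(mu, n) * (g / rep_len(theta, n))^(1 / rep_len(nu, n))
  })
}
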