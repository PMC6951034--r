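# Count observation families: Poisson, zero-inflated Poisson (ZIP),
# negative binomial (mean/size parameterization: variance mu + mu^2/size).

.check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("counts must be finite non-negative integers")
  invisible(y)
}

.check_family <- function(family) {
  match.arg(family, c("poisson", "zip", "negbin"))
}

#' Per-observation log-likelihood for a count family
#'
#' @param y non-negative integer counts.
#' @param mu positive mean of the count process (for ZIP, the mean of the
#'   Poisson component).
#' @param family one of `"poisson"`, `"zip"`, `"negbin"`.
#' @param size negative-binomial size \eqn{n > 0}; variance is
#'   \eqn{\mu + \mu^2/n}.
#' @param zi zero-inflation probability \eqn{\pi_0 \in [0, 1)}: extra mass at
#'   zero, so \eqn{P(y=0) = \pi_0 + (1-\pi_0) e^{-\mu}}.
#' @return numeric vector of log densities, one per observation.
#' @export
count_loglik <- function(y, mu, family = c("poisson", "zip", "negbin"),
                         size = NULL, zi = NULL) {
  family <- match.arg(family)
  .check_counts(y)
  if (any(!is.finite(mu) | mu <= 0)) {
    bad <- which(!is.finite(mu) | mu <= 0)[1]
    stop("non-finite or non-positive mean at row ", bad)
  }
  switch(family,
    poisson = stats::dpois(y, mu, log = TRUE),
    negbin = {
      stopifnot(!is.null(size), size > 0)
      stats::dnbinom(y, size = size, mu = mu, log = TRUE)
    },
    zip = {
      stopifnot(!is.null(zi), zi >= 0, zi < 1)
      ll <- log1p(-zi) + stats::dpois(y, mu, log = TRUE)
      z <- y == 0
      # log(zi + (1-zi) exp(-mu)); at zi = 0 this is exactly -mu
      if (any(z)) ll[z] <- log(zi + exp(log1p(-zi) - mu[z]))
      ll
    }
  )
}

#' Mean of a count family on the observation scale
#' @inheritParams count_loglik
#' @export
count_mean <- function(mu, family = c("poisson", "zip", "negbin"),
                       size = NULL, zi = NULL) {
  family <- match.arg(family)
  if (family == "zip") (1 - zi) * mu else mu
}

#' Variance of a count family on the observation scale
#'
#' Poisson: \eqn{\mu}; negative binomial: \eqn{\mu + \mu^2/n}; ZIP:
#' \eqn{(1-\pi_0)\mu(1 + \pi_0\mu)}.
#' @inheritParams count_loglik
#' @export
count_variance <- function(mu, family = c("poisson", "zip", "negbin"),
                           size = NULL, zi = NULL) {
  family <- match.arg(family)
  switch(family,
    poisson = mu,
    negbin = mu + mu^2 / size,
    zip = (1 - zi) * mu * (1 + zi * mu)
  )
}

#' Simulate counts from a family
#' @param n number of draws; recycled against `mu`.
#' @inheritParams count_loglik
#' @export
count_simulate <- function(n, mu, family = c("poisson", "zip", "negbin"),
                           size = NULL, zi = NULL) {
  family <- match.arg(family)
  switch(family,
    poisson = stats::rpois(n, mu),
    negbin = stats::rnbinom(n, size = size, mu = mu),
    zip = ifelse(stats::runif(n) < zi, 0L, stats::rpois(n, mu))
  )
}
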