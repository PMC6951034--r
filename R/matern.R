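#' Matern covariance function
#'
#' Stationary Matern covariance \eqn{C(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
#' (\kappa d)^\nu K_\nu(\kappa d)} with \eqn{\kappa = \sqrt{8\nu}/\rho}, so that
#' `range` is the distance at which the correlation has dropped to about 0.1
#' (the convention used for 2-D Gaussian random fields with smoothness
#' \eqn{\nu = 1}). At \eqn{d = 0} the covariance equals \eqn{\sigma^2} exactly.
#'
#' @param d numeric vector or matrix of distances (km); a distance matrix must
#'   be symmetric with a zero diagonal.
#' @param range correlation range \eqn{\rho > 0} (km).
#' @param sd marginal standard deviation \eqn{\sigma \ge 0} of the field.
#' @param nu smoothness; fixed default 1 (the 2-D SPDE-style default).
#' @param jitter relative nugget added to the diagonal of a distance *matrix*
#'   result (times \eqn{\sigma^2}) so the matrix stays numerically positive
#'   definite under Cholesky factorization.
#' @return covariance values with the same shape as `d`.
#' @examples
#' matern_cov(0, range = 1, sd = 2)          # = 4
#' matern_cov(1, range = 1, sd = 1)          # ~ 0.14 (range convention)
#' @export
matern_cov <- function(d, range, sd, nu = 1, jitter = 1e-8) {
  stopifnot(is.numeric(d), range > 0, sd >= 0, nu > 0)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-10)
      stop("distance matrix must be symmetric")
    if (any(diag(d) != 0))
      stop("distance matrix must have a zero diagonal")
  }
  C <- .matern_k(d, range, sd, nu)
  if (is.matrix(C)) diag(C) <- diag(C) + jitter * sd^2
  C
}

# covariance kernel without self-matrix validation or jitter: used for
# rectangular cross-covariance blocks in kriging
.matern_k <- function(d, range, sd, nu = 1) {
  if (any(d < 0)) stop("distances must be non-negative")
  kappa <- sqrt(8 * nu) / range
  x <- kappa * d
  C <- d
  pos <- x > 0
  C[!pos] <- 1
  C[pos] <- 2^(1 - nu) / gamma(nu) * x[pos]^nu * besselK(x[pos], nu)
  sd^2 * C
}

#' Penalized-complexity prior on a Matern correlation range
#'
#' PC prior with density \eqn{\pi(\rho) = (\lambda/\rho^2) e^{-\lambda/\rho}}
#' and CDF \eqn{P(\rho < r) = e^{-\lambda/r}}. The rate is calibrated from an
#' interpretable tail statement \eqn{P(\rho < \rho_0) = p}, giving
#' \eqn{\lambda = -\rho_0 \log p}.
#'
#' @param range_ref reference range \eqn{\rho_0 > 0} (km).
#' @param prob_below calibration probability \eqn{p = P(\rho < \rho_0)},
#'   in (0, 1).
#' @return a list with `lambda` and functions `d` (density), `p` (CDF),
#'   `q` (quantile) and `logd` (log density).
#' @examples
#' pr <- pc_prior_range(10, 0.95)
#' pr$p(10)   # = 0.95 by construction
#' @export
pc_prior_range <- function(range_ref, prob_below) {
  stopifnot(range_ref > 0, prob_below > 0, prob_below < 1)
  lambda <- -range_ref * log(prob_below)
  list(
    lambda = lambda,
    d = function(r) ifelse(r > 0, lambda / r^2 * exp(-lambda / r), 0),
    logd = function(r) ifelse(r > 0, log(lambda) - 2 * log(r) - lambda / r, -Inf),
    p = function(r) ifelse(r > 0, exp(-lambda / r), 0),
    q = function(pr) -lambda / log(pr)
  )
}

#' Penalized-complexity prior on a random-effect standard deviation
#'
#' Exponential PC prior \eqn{\pi(\sigma) = \lambda e^{-\lambda\sigma}},
#' calibrated from \eqn{P(\sigma > \sigma_0) = p}, giving
#' \eqn{\lambda = -\log(p)/\sigma_0}. Shrinks toward the base model
#' \eqn{\sigma = 0} (no spatial effect).
#'
#' @param sd_ref reference standard deviation \eqn{\sigma_0 > 0}.
#' @param prob_above calibration probability \eqn{p = P(\sigma > \sigma_0)}.
#' @return a list with `lambda` and functions `d`, `p` (upper-tail
#'   probability), `q` and `logd`.
#' @examples
#' ps <- pc_prior_sd(0.5, 0.05)
#' ps$p(0.5)  # = 0.05
#' @export
pc_prior_sd <- function(sd_ref, prob_above) {
  stopifnot(sd_ref > 0, prob_above > 0, prob_above < 1)
  lambda <- -log(prob_above) / sd_ref
  list(
    lambda = lambda,
    d = function(s) stats::dexp(s, rate = lambda),
    logd = function(s) stats::dexp(s, rate = lambda, log = TRUE),
    p = function(s) stats::pexp(s, rate = lambda, lower.tail = FALSE),
    q = function(pr) stats::qexp(1 - pr, rate = lambda)
  )
}

#' Bundle of priors for the spatial count model
#'
#' Collects the PC priors on the Matern range and field standard deviation,
#' the Gaussian prior standard deviation for fixed effects on the standardized
#' scale, the PC-style exponential prior rate on \eqn{1/\sqrt{n}} for the
#' negative-binomial size (shrinking toward the Poisson base model, calibrated
#' so that \eqn{P(n < 1) = 0.05} by default), and the Beta prior for a
#' zero-inflation probability.
#'
#' @param range_ref,range_prob calibration of the range prior,
#'   \eqn{P(\rho < \rho_0) = p_\rho}; defaults 10 km and 0.95.
#' @param sd_ref,sd_prob calibration of the field-sd prior,
#'   \eqn{P(\sigma > \sigma_0) = p_\sigma}; defaults 0.5 and 0.05.
#' @param beta_sd Gaussian prior sd for regression coefficients (standardized
#'   covariates); default 10.
#' @param size_prob prior probability that the NB size is below 1; default 0.05.
#' @param zi_shape1,zi_shape2 Beta prior for the zero-inflation probability;
#'   default Beta(1, 1).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(range_ref = 10, range_prob = 0.95,
                       sd_ref = 0.5, sd_prob = 0.05,
                       beta_sd = 10, size_prob = 0.05,
                       zi_shape1 = 1, zi_shape2 = 1) {
  stopifnot(beta_sd > 0, size_prob > 0, size_prob < 1)
  structure(list(
    range = pc_prior_range(range_ref, range_prob),
    sd = pc_prior_sd(sd_ref, sd_prob),
    range_ref = range_ref, range_prob = range_prob,
    sd_ref = sd_ref, sd_prob = sd_prob,
    beta_sd = beta_sd,
    # P(n < 1) = P(1/sqrt(n) > 1) = exp(-lambda) = size_prob
    size_lambda = -log(size_prob),
    zi_shape1 = zi_shape1, zi_shape2 = zi_shape2
  ), class = "prior_spec")
}

# log prior for NB size on the log-size scale:
# theta = 1/sqrt(n) ~ Exp(lambda); |d theta / d log n| = theta / 2
.log_prior_size <- function(log_size, lambda) {
  theta <- exp(-0.5 * log_size)
  log(lambda) - lambda * theta + log(theta / 2)
}

#' Pairwise Euclidean distance matrix for projected site coordinates
#'
#' @param coords two-column matrix or data frame of easting/northing in km.
#' @return symmetric distance matrix in km.
#' @export
site_distances <- function(coords) {
  coords <- as.matrix(coords[, 1:2])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  as.matrix(stats::dist(coords))
}
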