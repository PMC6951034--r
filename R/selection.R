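# Spike-and-slab (NMIG-style) Bayesian variable selection for count
# regression: beta_j | gamma_j ~ N(0, gamma_j v1 + (1 - gamma_j) v0),
# gamma_j ~ Bernoulli(w). Candidates are ranked by posterior inclusion
# probability E[gamma_j | y]; the final choice keeps, per weather variable,
# only the lag with the largest scaled effect, then takes the six largest
# absolute scaled effects among the top inclusion probabilities.

#' Spike-and-slab prior settings
#'
#' @param spike_sd standard deviation of the near-zero spike component;
#'   default 0.005.
#' @param slab_sd standard deviation of the diffuse slab; default 2.5
#'   (weakly informative on standardized covariates).
#' @param inclusion_prior prior inclusion probability w; default 0.5.
#' @return object of class `spike_slab_prior`.
#' @export
spike_slab_prior <- function(spike_sd = 0.005, slab_sd = 2.5,
                             inclusion_prior = 0.5) {
  stopifnot(spike_sd > 0, slab_sd > spike_sd,
            inclusion_prior > 0, inclusion_prior < 1)
  structure(list(spike_sd = spike_sd, slab_sd = slab_sd,
                 w = inclusion_prior), class = "spike_slab_prior")
}

# Gibbs update of gamma_j given beta_j: depends only on the prior mixture.
.gamma_prob <- function(beta, prior) {
  l1 <- log(prior$w) + stats::dnorm(beta, 0, prior$slab_sd, log = TRUE)
  l0 <- log1p(-prior$w) + stats::dnorm(beta, 0, prior$spike_sd, log = TRUE)
  1 / (1 + exp(l0 - l1))
}

#' Spike-and-slab variable selection by MCMC
#'
#' Runs MCMC over \eqn{(\beta, \gamma)} for a count (negative-binomial by
#' default) or Gaussian regression with the NMIG two-component normal
#' mixture prior on each candidate coefficient. For the Gaussian working
#' likelihood with known error sd, the \eqn{\beta} updates are exact
#' conjugate Gibbs draws (used for calibration against brute-force
#' enumeration); for count likelihoods they are adaptive random-walk
#' Metropolis steps. The intercept always carries the slab prior; for the
#' negative-binomial likelihood a diffuse prior is placed on the size.
#'
#' @param y response: non-negative integer counts, or numeric for
#'   `family = "gaussian"`.
#' @param X candidate design matrix (standardized columns), no intercept.
#' @param prior a [spike_slab_prior()].
#' @param n_iter,burn_in MCMC length; `n_iter > burn_in >= 0`.
#' @param seed integer seed.
#' @param family `"negbin"` (default) or `"gaussian"` (working likelihood
#'   with known `sigma`, for calibration studies).
#' @param sigma Gaussian error sd (only for `family = "gaussian"`).
#' @return object of class `selection_result`: data frame `$ranking` with
#'   `term`, `inclusion_probability`, `scaled_effect` (posterior mean of
#'   \eqn{\beta_j}) and `rank`, plus the kept draws.
#' @export
spike_slab_select <- function(y, X, prior = spike_slab_prior(),
                              n_iter = 4000, burn_in = 1000, seed = 1L,
                              family = c("negbin", "gaussian"), sigma = 1) {
  family <- match.arg(family)
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (family != "gaussian") .check_counts(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant candidate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (qr(X)$rank < ncol(X)) stop("candidate design is rank deficient")
  set.seed(seed)
  N <- length(y); p <- ncol(X)

  ## initialization
  if (family == "gaussian") {
    beta0 <- mean(y)
    beta <- drop(stats::coef(stats::lm.fit(X, y - beta0)))
    lsize <- 0
  } else {
    ml <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::poisson())$coefficients),
      error = function(e) c(log(mean(y) + 0.01), rep(0, p)))
    beta0 <- ml[1]; beta <- ml[-1]
    beta[!is.finite(beta)] <- 0
    mu0 <- mean(y); v0 <- stats::var(y)
    lsize <- log(if (v0 > mu0) max(0.2, min(50, mu0^2 / (v0 - mu0))) else 10)
  }
  gam_st <- as.integer(abs(beta) > 0.05)
  eta <- beta0 + drop(X %*% beta)
  llik <- function(eta, lsize) {
    if (family == "gaussian")
      sum(stats::dnorm(y, eta, sigma, log = TRUE))
    else .ll_sum(y, eta, "negbin", exp(lsize), NULL)
  }
  cur_ll <- llik(eta, lsize)

  s_b <- rep(0.1, p); s_b0 <- 0.05; s_sz <- 0.2
  slab0_sd <- 10   # intercept prior sd
  keep <- n_iter - burn_in
  G <- matrix(0L, keep, p); Bd <- matrix(0, keep, p)
  k <- 0L
  XtX <- if (family == "gaussian") colSums(X^2)

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn_in
    g <- min(0.05, 2 / it^0.7)

    ## gamma | beta (exact Gibbs, prior-only)
    pg <- .gamma_prob(beta, prior)
    gam_st <- as.integer(stats::runif(p) < pg)
    psd <- ifelse(gam_st == 1L, prior$slab_sd, prior$spike_sd)

    if (family == "gaussian") {
      ## conjugate Gibbs for beta_j and intercept
      for (j in seq_len(p)) {
        r <- y - eta + X[, j] * beta[j]
        prec <- XtX[j] / sigma^2 + 1 / psd[j]^2
        m <- (sum(X[, j] * r) / sigma^2) / prec
        bnew <- stats::rnorm(1, m, 1 / sqrt(prec))
        eta <- eta + X[, j] * (bnew - beta[j])
        beta[j] <- bnew
      }
      r <- y - eta + beta0
      prec <- N / sigma^2 + 1 / slab0_sd^2
      m <- (sum(r) / sigma^2) / prec
      b0new <- stats::rnorm(1, m, 1 / sqrt(prec))
      eta <- eta + (b0new - beta0); beta0 <- b0new
      cur_ll <- llik(eta, lsize)
    } else {
      ## random-walk Metropolis for each beta_j
      for (j in seq_len(p)) {
        del <- s_b[j] * stats::rnorm(1)
        bnew <- beta[j] + del
        eta_new <- eta + X[, j] * del
        ll_new <- llik(eta_new, lsize)
        dlp <- ll_new - cur_ll +
          stats::dnorm(bnew, 0, psd[j], log = TRUE) -
          stats::dnorm(beta[j], 0, psd[j], log = TRUE)
        a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
        if (stats::runif(1) < a) {
          beta[j] <- bnew; eta <- eta_new; cur_ll <- ll_new
        }
        if (adapting) s_b[j] <- s_b[j] * exp(g * (a - 0.44))
      }
      ## intercept
      del <- s_b0 * stats::rnorm(1)
      eta_new <- eta + del
      ll_new <- llik(eta_new, lsize)
      dlp <- ll_new - cur_ll +
        stats::dnorm(beta0 + del, 0, slab0_sd, log = TRUE) -
        stats::dnorm(beta0, 0, slab0_sd, log = TRUE)
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) {
        beta0 <- beta0 + del; eta <- eta_new; cur_ll <- ll_new
      }
      if (adapting) s_b0 <- s_b0 * exp(g * (a - 0.44))
      ## NB size, diffuse prior N(0, 3^2) on log size
      del <- s_sz * stats::rnorm(1)
      ll_new <- llik(eta, lsize + del)
      dlp <- ll_new - cur_ll +
        stats::dnorm(lsize + del, 0, 3, log = TRUE) -
        stats::dnorm(lsize, 0, 3, log = TRUE)
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) { lsize <- lsize + del; cur_ll <- ll_new }
      if (adapting) s_sz <- s_sz * exp(g * (a - 0.44))
    }
    if (!is.finite(cur_ll))
      stop("divergent chain (non-finite log-posterior) at iteration ", it)

    if (it > burn_in) {
      k <- k + 1L
      G[k, ] <- gam_st
      Bd[k, ] <- beta
    }
  }

  ranking <- data.frame(
    term = colnames(X),
    inclusion_probability = colMeans(G),
    scaled_effect = colMeans(Bd),
    row.names = NULL
  )
  ranking <- ranking[order(-ranking$inclusion_probability,
                           -abs(ranking$scaled_effect), ranking$term), ]
  ranking$rank <- seq_len(nrow(ranking))
  structure(list(ranking = ranking, gamma = G, beta = Bd,
                 prior = prior, family = family),
            class = "selection_result")
}

#' Choose the final six predictors
#'
#' Two-stage rule: within each weather-variable group keep only the lag with
#' the largest absolute scaled effect; restrict to the `k_top` candidates
#' with the highest posterior inclusion probabilities; return the `n_choose`
#' with the largest absolute scaled effects. Ties at the final slot break
#' alphabetically (deterministic, logged via message).
#'
#' @param result a `selection_result`.
#' @param weather_groups named list mapping each weather variable to its lag
#'   column names, e.g. `list(temperature = c("temperature_lag0", ...))`.
#' @param k_top size of the inclusion-probability shortlist; default 12.
#' @param n_choose number of predictors to return; default 6.
#' @return character vector of chosen column names (all candidates, with a
#'   warning, if fewer than `n_choose` remain).
#' @export
choose_top_six <- function(result, weather_groups = list(), k_top = 12,
                           n_choose = 6) {
  stopifnot(inherits(result, "selection_result"))
  r <- result$ranking
  drop_cols <- character()
  for (grp in weather_groups) {
    grp <- intersect(grp, r$term)
    if (length(grp) < 2) next
    eff <- abs(r$scaled_effect[match(grp, r$term)])
    keep <- grp[which.max(eff)]
    drop_cols <- c(drop_cols, setdiff(grp, keep))
  }
  r <- r[!r$term %in% drop_cols, ]
  r <- r[order(-r$inclusion_probability, r$term), ]
  shortlist <- utils::head(r, k_top)
  ord <- order(-abs(shortlist$scaled_effect), shortlist$term)
  shortlist <- shortlist[ord, ]
  if (nrow(shortlist) > n_choose) {
    cut <- abs(shortlist$scaled_effect[n_choose])
    if (any(abs(shortlist$scaled_effect[-seq_len(n_choose)]) == cut))
      message("tie in |scaled_effect| at the final slot; ",
              "broken alphabetically")
  }
  if (nrow(shortlist) < n_choose) {
    warning("fewer than ", n_choose, " candidates available; returning all")
    return(shortlist$term)
  }
  shortlist$term[seq_len(n_choose)]
}
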