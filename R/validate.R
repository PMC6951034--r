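# Posterior-predictive simulation study and scaled-residual analysis.

#' Posterior-predictive ensemble and count-histogram bands
#'
#' Draws `n_sims` parameter sets from the posterior (with replacement if
#' fewer draws are stored, with a message), simulates a full replicate count
#' dataset from each, and tabulates the frequency of every count value with
#' pointwise 2.5/97.5-percentile bands. A model whose observed count
#' histogram lies within the band across count values has a good predictive
#' fit.
#'
#' @param fit a `trap_fit`.
#' @param n_sims number of simulated datasets; default 1000.
#' @param seed integer seed.
#' @param max_count upper end of the tabulated count values; defaults to the
#'   larger of the observed maximum and the 99th percentile of simulated
#'   counts.
#' @return object of class `predictive_ensemble`: `$bands` (data frame
#'   `count`, `observed`, `lower`, `median`, `upper`, `covered`), `$sims`
#'   (matrix of simulated datasets, observations in rows) and
#'   `$coverage` (fraction of count bins whose observed frequency is within
#'   the band).
#' @export
posterior_predictive <- function(fit, n_sims = 1000, seed = 1L,
                                 max_count = NULL) {
  stopifnot(inherits(fit, "trap_fit"))
  set.seed(seed)
  nd <- length(fit$draws$deviance)
  if (nd < n_sims)
    message("only ", nd, " posterior draws; sampling with replacement")
  take <- sample.int(nd, n_sims, replace = nd < n_sims)
  N <- length(fit$y)
  sims <- matrix(0L, N, n_sims)
  for (j in seq_along(take)) {
    i <- take[j]
    eta <- drop(fit$X %*% fit$draws$beta[i, ])
    if (fit$spatial) eta <- eta + fit$draws$u[i, ][fit$site_idx]
    sims[, j] <- count_simulate(N, exp(eta), fit$family,
                                size = fit$draws$size[i],
                                zi = fit$draws$zi[i])
  }
  if (is.null(max_count))
    max_count <- max(max(fit$y), stats::quantile(sims, 0.99))
  vals <- 0:max_count
  tab <- function(v) tabulate(factor(pmin(v, max_count), levels = vals),
                              nbins = length(vals))
  obs <- tab(fit$y)
  freq <- apply(sims, 2, tab)
  qs <- apply(freq, 1, stats::quantile, c(0.025, 0.5, 0.975))
  bands <- data.frame(count = vals, observed = obs,
                      lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
  bands$covered <- bands$observed >= bands$lower & bands$observed <= bands$upper
  structure(list(bands = bands, sims = sims,
                 coverage = mean(bands$covered)),
            class = "predictive_ensemble")
}

#' Scaled (Pearson) residuals against a simulation envelope
#'
#' Computes Pearson residuals \eqn{r_i = (y_i - \hat m_i)/\sqrt{V(\hat m_i)}}
#' for the observed data at the posterior-mean fit, the same residuals for
#' every simulated dataset of the ensemble, and compares the observed
#' residual quantiles to the pointwise 2.5/97.5 envelope of the simulated
#' ones. Exceedances flag systematic over- or under-prediction.
#'
#' @param fit a `trap_fit`.
#' @param ensemble a `predictive_ensemble` from [posterior_predictive()]; if
#'   missing, one of 200 simulations is created.
#' @param probs quantiles compared; default the deciles 0.05..0.95.
#' @param seed seed for the default ensemble.
#' @return list: `residuals` (observed), `quantiles` (data frame `prob`,
#'   `observed`, `lower`, `upper`, `flagged`), `n_flagged`.
#' @export
scaled_residuals <- function(fit, ensemble = NULL,
                             probs = seq(0.05, 0.95, by = 0.05), seed = 1L) {
  stopifnot(inherits(fit, "trap_fit"))
  if (is.null(ensemble))
    ensemble <- posterior_predictive(fit, n_sims = 200, seed = seed)
  mu_hat <- exp(fit$eta_mean)
  size_hat <- mean(fit$draws$size); zi_hat <- mean(fit$draws$zi)
  m <- count_mean(mu_hat, fit$family, size = size_hat, zi = zi_hat)
  v <- count_variance(mu_hat, fit$family, size = size_hat, zi = zi_hat)
  r_obs <- (fit$y - m) / sqrt(v)
  r_sim <- (ensemble$sims - m) / sqrt(v)
  q_obs <- stats::quantile(r_obs, probs, names = FALSE)
  q_sim <- apply(r_sim, 2, stats::quantile, probs, names = FALSE)
  env <- apply(q_sim, 1, stats::quantile, c(0.025, 0.975), names = FALSE)
  out <- data.frame(prob = probs, observed = q_obs,
                    lower = env[1, ], upper = env[2, ])
  out$flagged <- out$observed < out$lower | out$observed > out$upper
  list(residuals = r_obs, quantiles = out, n_flagged = sum(out$flagged))
}
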