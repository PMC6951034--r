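# User-facing model fitting, DIC, overdispersion and model comparison.

#' Fit a Bayesian count model with an optional Matern spatial random effect
#'
#' Fits \eqn{y_i \sim \mathrm{family}(\mu_i)}, \eqn{\log\mu_i = x_i^T\beta +
#' u(s_i)}, where the site-level field \eqn{u} has a Matern(\eqn{\nu=1})
#' covariance with PC priors on its range and standard deviation, by adaptive
#' Metropolis-within-Gibbs MCMC. The negative-binomial size carries a
#' PC-style exponential prior on \eqn{1/\sqrt{n}} (shrinking toward Poisson)
#' and a ZIP zero-inflation probability a Beta prior. Chains are initialized
#' from a (jittered) maximum-likelihood GLM fit.
#'
#' @param y non-negative integer counts.
#' @param X covariate matrix or data frame (standardized scale); an intercept
#'   column is added automatically.
#' @param sites site identifier per observation (required when
#'   `spatial = TRUE`).
#' @param coords data frame with one row per site: `site_id`, `easting_km`,
#'   `northing_km` (projected km).
#' @param family `"negbin"`, `"poisson"` or `"zip"`.
#' @param spatial include the spatial random effect?
#' @param priors a [prior_spec()].
#' @param chains number of chains (>= 2).
#' @param iter total iterations per chain; `warmup` of them are discarded and
#'   used for proposal adaptation.
#' @param warmup,thin warmup length and post-warmup thinning interval.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param on_nonconvergence `"error"` (default) aborts when any monitored
#'   split-\eqn{\hat R} exceeds 1.05; `"warn"` downgrades to a warning.
#' @return object of class `trap_fit`: posterior draws (`$draws`), data,
#'   convergence diagnostics (`$diagnostics`), pointwise posterior-mean
#'   linear predictor, per-draw deviance and Pearson dispersion.
#' @export
fit_count_model <- function(y, X, sites = NULL, coords = NULL,
                            family = c("negbin", "poisson", "zip"),
                            spatial = TRUE, priors = prior_spec(),
                            chains = 2, iter = 3000,
                            warmup = floor(iter / 2),
                            thin = max(1L, floor((iter - warmup) / 750)),
                            seed = 1L,
                            on_nonconvergence = c("error", "warn")) {
  family <- match.arg(family)
  on_nonconvergence <- match.arg(on_nonconvergence)
  .check_counts(y)
  if (chains < 2) stop("need at least 2 chains for convergence diagnostics")
  if (iter - warmup < 200) stop("too few post-warmup iterations")
  X <- as.matrix(X)   # data-frame colnames (incl. "a:b") kept verbatim
  if (!is.numeric(X) || !all(is.finite(X)))
    stop("design must be numeric with finite values")
  if ("(Intercept)" %in% colnames(X)) {
    Xf <- X
  } else {
    Xf <- cbind("(Intercept)" = 1, X)
  }
  if (qr(Xf)$rank < ncol(Xf)) stop("design matrix is rank deficient")
  N <- length(y); p <- ncol(Xf)
  if (N <= p) stop("more parameters than observations")

  site_idx <- site_list <- D <- NULL
  S <- 0L
  if (spatial) {
    if (is.null(sites) || is.null(coords))
      stop("spatial = TRUE requires `sites` and `coords`")
    coords <- as.data.frame(coords)
    sid <- as.character(coords$site_id)
    site_idx <- match(as.character(sites), sid)
    if (anyNA(site_idx)) stop("observation sites missing from `coords`")
    S <- length(sid)
    if (length(unique(site_idx)) < 3)
      stop("spatial model needs at least 3 distinct sites")
    site_list <- split(seq_len(N), factor(site_idx, levels = seq_len(S)))
    D <- site_distances(coords[, c("easting_km", "northing_km")])
  }

  ## initial values from an ML fit
  b0 <- tryCatch(
    suppressWarnings(stats::glm.fit(Xf, y, family = stats::poisson())$coefficients),
    error = function(e) NULL)
  if (is.null(b0) || any(!is.finite(b0))) {
    b0 <- c(log(mean(y) + 0.01), rep(0, p - 1))
  }
  mu0 <- mean(y); v0 <- stats::var(y)
  size0 <- if (v0 > mu0) max(0.2, min(50, mu0^2 / (v0 - mu0))) else 10
  zi0 <- min(0.8, max(0.05, mean(y == 0) - exp(-mu0)))

  run_one <- function(ch) {
    set.seed(seed + 104729L * ch)
    init <- list(
      beta = b0 + stats::rnorm(p, 0, 0.05),
      u = if (spatial) stats::rnorm(S, 0, 0.1) else numeric(0),
      range = if (spatial) max(0.05, exp(log(max(D) / 5) + stats::rnorm(1, 0, 0.3))) else 1,
      sd = if (spatial) exp(log(0.3) + stats::rnorm(1, 0, 0.3)) else 1,
      size = size0 * exp(stats::rnorm(1, 0, 0.2)),
      zi = min(0.95, max(0.02, zi0 * exp(stats::rnorm(1, 0, 0.1))))
    )
    .run_chain(y, Xf, site_idx, site_list, D, family, spatial, priors,
               n_iter = iter, warmup = warmup, thin = thin, init = init,
               chain_seed = seed + 7919L * ch)
  }
  res <- lapply(seq_len(chains), run_one)

  nk <- min(vapply(res, `[[`, 0L, "n_kept"))
  take <- function(f) do.call(rbind, lapply(res, function(r) {
    m <- r[[f]]; if (is.matrix(m)) m[seq_len(nk), , drop = FALSE] else NULL
  }))
  takev <- function(f) unlist(lapply(res, function(r) r[[f]][seq_len(nk)]))
  draws <- list(
    beta = take("beta"),
    u = if (spatial) take("u"),
    range = takev("range"), sd = takev("sd"),
    size = takev("size"), zi = takev("zi"),
    deviance = takev("deviance"), pearson = takev("pearson"),
    chain = rep(seq_len(chains), each = nk)
  )
  eta_mean <- Reduce(`+`, lapply(res, `[[`, "eta_mean")) / chains

  ## convergence diagnostics on monitored scalars
  mon <- list()
  for (j in seq_len(p))
    mon[[colnames(Xf)[j]]] <- vapply(res, function(r) r$beta[seq_len(nk), j],
                                     numeric(nk))
  if (spatial) {
    mon[["range"]] <- vapply(res, function(r) log(r$range[seq_len(nk)]), numeric(nk))
    mon[["sd"]] <- vapply(res, function(r) log(r$sd[seq_len(nk)]), numeric(nk))
  }
  if (family == "negbin")
    mon[["size"]] <- vapply(res, function(r) log(r$size[seq_len(nk)]), numeric(nk))
  if (family == "zip")
    mon[["zi"]] <- vapply(res, function(r) r$zi[seq_len(nk)], numeric(nk))
  diagnostics <- data.frame(
    param = names(mon),
    rhat = vapply(mon, .split_rhat, 0),
    ess = vapply(mon, .ess, 0),
    row.names = NULL
  )
  bad <- diagnostics$param[is.finite(diagnostics$rhat) & diagnostics$rhat > 1.05]
  if (length(bad)) {
    msg <- paste0("chains did not converge (split-Rhat > 1.05): ",
                  paste(bad, collapse = ", "),
                  "; increase `iter` or check the model")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  structure(list(
    draws = draws, y = y, X = Xf, sites = sites, coords = coords,
    site_idx = site_idx, D = D, family = family, spatial = spatial,
    priors = priors, eta_mean = eta_mean, diagnostics = diagnostics,
    chains = chains, iter = iter, warmup = warmup, thin = thin, seed = seed,
    accept = lapply(res, `[[`, "accept")
  ), class = "trap_fit")
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\bar\theta)}, where
#' \eqn{\bar D} is the posterior mean deviance and \eqn{\bar\theta} the
#' posterior mean of the linear predictor and family parameters.
#'
#' @param fit a `trap_fit` with at least 100 post-warmup draws.
#' @return list with `dic`, `pd`, `d_bar`, `d_hat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "trap_fit"))
  dev <- fit$draws$deviance
  if (length(dev) < 100) stop("need at least 100 post-warmup draws for DIC")
  if (any(!is.finite(dev))) stop("non-finite deviance draws")
  d_bar <- mean(dev)
  d_hat <- -2 * sum(count_loglik(fit$y, exp(fit$eta_mean), fit$family,
                                 size = mean(fit$draws$size),
                                 zi = mean(fit$draws$zi)))
  pd <- d_bar - d_hat
  list(dic = d_bar + pd, pd = pd, d_bar = d_bar, d_hat = d_hat)
}

#' Pearson overdispersion statistic
#'
#' Per posterior draw, \eqn{\sum_i (y_i - \hat m_i)^2 / V(\hat m_i)} divided
#' by \eqn{N - p} (fixed-effect parameters only); the point estimate is the
#' posterior mean, the interval the 2.5/97.5 percentiles across draws. A
#' value near 1 indicates the family's variance matches the data.
#'
#' @param fit a `trap_fit`.
#' @return list with `estimate`, `lower`, `upper`.
#' @export
overdispersion_stat <- function(fit) {
  stopifnot(inherits(fit, "trap_fit"))
  ps <- fit$draws$pearson
  q <- stats::quantile(ps, c(0.025, 0.975), names = FALSE)
  list(estimate = mean(ps), lower = q[1], upper = q[2])
}

#' Posterior summaries of regression coefficients
#'
#' Posterior mean, sd, equal-tailed 95% credible interval, and an
#' importance flag: a coefficient is "statistically important" when its 95%
#' credible interval excludes zero.
#'
#' @param fit a `trap_fit`.
#' @return data frame with one row per coefficient.
#' @export
coef_summary <- function(fit) {
  stopifnot(inherits(fit, "trap_fit"))
  B <- fit$draws$beta
  q <- t(apply(B, 2, stats::quantile, c(0.025, 0.975)))
  data.frame(
    term = colnames(B),
    mean = colMeans(B),
    sd = apply(B, 2, stats::sd),
    lower = q[, 1], upper = q[, 2],
    important = q[, 1] > 0 | q[, 2] < 0,
    row.names = NULL
  )
}

#' Posterior summaries of hyperparameters
#' @param fit a `trap_fit`.
#' @return data frame of posterior median and 95% interval for the spatial
#'   range (km), field sd, NB size and/or zero-inflation probability.
#' @export
hyper_summary <- function(fit) {
  stopifnot(inherits(fit, "trap_fit"))
  pars <- list()
  if (fit$spatial) pars <- c(pars, list(range_km = fit$draws$range,
                                        spatial_sd = fit$draws$sd))
  if (fit$family == "negbin") pars <- c(pars, list(nb_size = fit$draws$size))
  if (fit$family == "zip") pars <- c(pars, list(zero_inflation = fit$draws$zi))
  do.call(rbind, lapply(names(pars), function(nm) {
    q <- stats::quantile(pars[[nm]], c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(param = nm, median = q[1], lower = q[2], upper = q[3])
  }))
}

#' Fit and rank a set of model specifications by DIC
#'
#' Fits each specification (family + spatial flag) to the same data and
#' returns a table ordered by DIC with the best model flagged, alongside the
#' per-model coefficient importance calls.
#'
#' @param specs list of lists with elements `family`, `spatial` and
#'   optionally `label`.
#' @param y,X,sites,coords shared data (see [fit_count_model()]).
#' @param ... further arguments passed to [fit_count_model()] (priors,
#'   chains, iter, seed, ...).
#' @return list with `table` (data frame: label, family, spatial, dic, pd,
#'   best), `fits` and `coefficients` (per-model [coef_summary()]).
#' @export
compare_models <- function(specs, y, X, sites = NULL, coords = NULL, ...) {
  if (length(specs) < 2) stop("need at least 2 model specifications")
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    lab <- if (!is.null(sp$label)) sp$label else
      paste0(sp$family, if (isTRUE(sp$spatial)) "+spatial" else "")
    f <- tryCatch(
      fit_count_model(y, X, sites = sites, coords = coords,
                      family = sp$family, spatial = isTRUE(sp$spatial), ...),
      error = function(e) stop("model `", lab, "` failed: ",
                               conditionMessage(e)))
    d <- dic(f)
    fits[[i]] <- f
    rows[[i]] <- data.frame(label = lab, family = sp$family,
                            spatial = isTRUE(sp$spatial),
                            dic = d$dic, pd = d$pd)
  }
  tab <- do.call(rbind, rows)
  tab$best <- tab$dic == min(tab$dic)
  names(fits) <- tab$label
  list(table = tab[order(tab$dic), ], fits = fits,
       coefficients = lapply(fits, coef_summary))
}

#' @export
print.trap_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s count model%s: %d obs, %d draws (%d chains)\n",
              x$family, if (x$spatial) " + Matern spatial effect" else "",
              length(x$y), length(x$draws$deviance), x$chains))
  cat("Coefficients (posterior mean [95% CI]):\n")
  cs <- coef_summary(x)
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-28s %6.3f [%6.3f, %6.3f]%s\n", cs$term[i], cs$mean[i],
                cs$lower[i], cs$upper[i], if (cs$important[i]) " *" else ""))
  hs <- hyper_summary(x)
  if (!is.null(hs)) {
    cat("Hyperparameters (posterior median [95% CI]):\n")
    for (i in seq_len(nrow(hs)))
      cat(sprintf("  %-28s %6.3f [%6.3f, %6.3f]\n", hs$param[i], hs$median[i],
                  hs$lower[i], hs$upper[i]))
  }
  d <- dic(x); o <- overdispersion_stat(x)
  cat(sprintf("DIC %.2f (pD %.1f); overdispersion %.2f [%.2f, %.2f]\n",
              d$dic, d$pd, o$estimate, o$lower, o$upper))
  cat(sprintf("max split-Rhat %.3f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior mode of the fixed effects (non-spatial models)
#'
#' Maximizes the exact log posterior of a fitted non-spatial model over
#' \eqn{\beta} (and log size / logit zero-inflation where present) by
#' quasi-Newton optimization started at the posterior means. With the
#' default diffuse coefficient prior the mode essentially coincides with the
#' maximum-likelihood solution of the corresponding GLM.
#'
#' @param fit a non-spatial `trap_fit`.
#' @return named numeric vector of modal coefficient values.
#' @export
posterior_mode <- function(fit) {
  stopifnot(inherits(fit, "trap_fit"))
  if (fit$spatial) stop("posterior mode implemented for non-spatial fits only")
  p <- ncol(fit$X)
  has_size <- fit$family == "negbin"; has_zi <- fit$family == "zip"
  start <- colMeans(fit$draws$beta)
  if (has_size) start <- c(start, log(mean(fit$draws$size)))
  if (has_zi) start <- c(start, stats::qlogis(mean(fit$draws$zi)))
  negpost <- function(th) {
    beta <- th[seq_len(p)]
    size <- if (has_size) exp(th[p + 1]) else NULL
    zi <- if (has_zi) stats::plogis(th[length(th)]) else NULL
    eta <- drop(fit$X %*% beta)
    lp <- .ll_sum(fit$y, eta, fit$family, size, zi) +
      sum(stats::dnorm(beta, 0, fit$priors$beta_sd, log = TRUE))
    if (has_size) lp <- lp + .log_prior_size(th[p + 1], fit$priors$size_lambda)
    if (has_zi) lp <- lp +
      stats::dbeta(zi, fit$priors$zi_shape1, fit$priors$zi_shape2, log = TRUE) +
      log(zi * (1 - zi))
    -lp
  }
  opt <- stats::optim(start, negpost, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  stats::setNames(opt$par[seq_len(p)], colnames(fit$X))
}
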