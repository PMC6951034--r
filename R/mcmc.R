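# Adaptive Metropolis-within-Gibbs engine for the spatial count model.
#
# Model: y_i ~ family(mu_i, ...), log mu_i = x_i' beta + u(site_i),
#        u ~ N(0, Matern(range, sd, nu = 1)) over sites,
#        PC priors on (range, sd), N(0, beta_sd^2) on beta,
#        exponential PC-style prior on 1/sqrt(size), Beta prior on zi.
#
# Updates: joint adaptive random-walk on beta (covariance learned in warmup),
# per-site random-walk on u, a likelihood-invariant intercept/field swap move,
# a joint random-walk on (log range, log sd) with the Cholesky recomputed on
# proposal, and scalar random walks on log size / logit zi. All scales adapt
# by Robbins-Monro during warmup only.

.ll_sum <- function(y, eta, family, size, zi) {
  mu <- exp(eta)
  ll <- switch(family,
    poisson = stats::dpois(y, mu, log = TRUE),
    negbin  = stats::dnbinom(y, size = size, mu = mu, log = TRUE),
    zip = {
      l <- log1p(-zi) + stats::dpois(y, mu, log = TRUE)
      z <- y == 0L
      if (any(z)) l[z] <- log(zi + exp(log1p(-zi) - mu[z]))
      l
    })
  s <- sum(ll)
  if (is.finite(s)) s else -Inf
}

.pearson_stat <- function(y, eta, family, size, zi, p_fix) {
  mu <- exp(eta)
  m <- count_mean(mu, family, size = size, zi = zi)
  v <- count_variance(mu, family, size = size, zi = zi)
  sum((y - m)^2 / v) / (length(y) - p_fix)
}

.run_chain <- function(y, X, site_idx, site_list, D, family, spatial,
                       priors, n_iter, warmup, thin, init, chain_seed) {
  set.seed(chain_seed)
  N <- length(y); p <- ncol(X)
  S <- if (spatial) length(site_list) else 0L
  beta_sd <- priors$beta_sd

  beta <- init$beta
  u <- if (spatial) init$u else numeric(0)
  lrange <- log(init$range); lsd <- log(init$sd)
  lsize <- log(init$size); zi <- init$zi; lzi <- stats::qlogis(min(max(zi, 1e-4), 1 - 1e-4))
  size <- exp(lsize)

  eta <- drop(X %*% beta) + if (spatial) u[site_idx] else 0
  cur_ll <- .ll_sum(y, eta, family, size, zi)
  if (!is.finite(cur_ll)) stop("non-finite log-likelihood at initialization")

  # spatial prior state
  if (spatial) {
    upd_cov <- function(lr, ls) {
      C <- matern_cov(D, exp(lr), exp(ls))
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      list(ch = ch, logdet = 2 * sum(log(diag(ch))), Q = chol2inv(ch))
    }
    cs <- upd_cov(lrange, lsd)
    if (is.null(cs)) stop("singular spatial covariance at initialization; ",
                          "increase jitter or perturb coordinates")
    Q <- cs$Q; logdet <- cs$logdet
    Qu <- drop(Q %*% u); quad <- sum(u * Qu)
    rowQ <- rowSums(Q); sumQ <- sum(rowQ)
  }

  # adaptive proposal state
  s_bj <- rep(0.05, p)
  s_beta <- 0.1; Lb <- diag(2.4 / sqrt(p), p)
  bsum <- numeric(p); bcross <- matrix(0, p, p); bn <- 0
  s_u <- rep(0.5, S); s_swap <- 0.2; s_hyp <- c(1.0, 0.4); s_size <- 0.2
  s_zi <- 0.5
  gam <- function(t) min(0.05, 2 / t^0.7)

  n_keep <- length(seq(warmup + 1L, n_iter, by = thin))
  keep_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  keep_u <- if (spatial) matrix(NA_real_, n_keep, S) else NULL
  keep_range <- keep_sd <- keep_size <- keep_zi <- keep_dev <-
    keep_pearson <- numeric(n_keep)
  eta_sum <- numeric(N)
  acc <- c(beta = 0, u = 0, hyper = 0, size = 0, zi = 0, swap = 0)
  k <- 0L

  for (it in seq_len(n_iter)) {
    adapting <- it <= warmup
    g <- gam(it)

    ## --- beta: per-coordinate adaptive random walk ---
    for (j in seq_len(p)) {
      del <- s_bj[j] * stats::rnorm(1)
      eta_new <- eta + X[, j] * del
      ll_new <- .ll_sum(y, eta_new, family, size, zi)
      dlp <- ll_new - cur_ll +
        stats::dnorm(beta[j] + del, 0, beta_sd, log = TRUE) -
        stats::dnorm(beta[j], 0, beta_sd, log = TRUE)
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) {
        beta[j] <- beta[j] + del; eta <- eta_new; cur_ll <- ll_new
        acc["beta"] <- acc["beta"] + 1 / p
      }
      if (adapting) s_bj[j] <- s_bj[j] * exp(g * (a - 0.44))
    }

    ## --- beta: joint move with adapted covariance (helps correlated terms) ---
    prop <- beta + s_beta * drop(Lb %*% stats::rnorm(p))
    eta_new <- eta + drop(X %*% (prop - beta))
    ll_new <- .ll_sum(y, eta_new, family, size, zi)
    dlp <- ll_new - cur_ll +
      sum(stats::dnorm(prop, 0, beta_sd, log = TRUE)) -
      sum(stats::dnorm(beta, 0, beta_sd, log = TRUE))
    a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
    if (stats::runif(1) < a) {
      beta <- prop; eta <- eta_new; cur_ll <- ll_new
    }
    if (adapting) {
      s_beta <- s_beta * exp(g * (a - 0.25))
      bsum <- bsum + beta; bcross <- bcross + tcrossprod(beta); bn <- bn + 1
      if (bn >= 200 && it %% 100 == 0) {
        m <- bsum / bn
        V <- bcross / bn - tcrossprod(m) + diag(1e-9, p)
        Lb <- tryCatch(t(chol(V)), error = function(e) Lb)
      }
    }

    if (spatial) {
      ## --- u, site by site ---
      for (s in seq_len(S)) {
        del <- s_u[s] * stats::rnorm(1)
        idx <- site_list[[s]]
        eta_s <- eta[idx] + del
        dll <- .ll_sum(y[idx], eta_s, family, size, zi) -
               .ll_sum(y[idx], eta[idx], family, size, zi)
        dpr <- -0.5 * (2 * del * Qu[s] + del^2 * Q[s, s])
        a <- if (is.finite(dll + dpr)) min(1, exp(dll + dpr)) else 0
        if (stats::runif(1) < a) {
          u[s] <- u[s] + del; eta[idx] <- eta_s; cur_ll <- cur_ll + dll
          quad <- quad + 2 * del * Qu[s] + del^2 * Q[s, s]
          Qu <- Qu + Q[, s] * del
          acc["u"] <- acc["u"] + 1 / S
        }
        if (adapting) s_u[s] <- s_u[s] * exp(g * (a - 0.44))
      }

      ## --- intercept/field swap (likelihood-invariant) ---
      del <- s_swap * stats::rnorm(1)
      quad_new <- quad - 2 * del * sum(Qu) + del^2 * sumQ
      dlp <- stats::dnorm(beta[1] + del, 0, beta_sd, log = TRUE) -
             stats::dnorm(beta[1], 0, beta_sd, log = TRUE) -
             0.5 * (quad_new - quad)
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) {
        beta[1] <- beta[1] + del; u <- u - del
        Qu <- Qu - del * rowQ; quad <- quad_new
        acc["swap"] <- acc["swap"] + 1
      }
      if (adapting) s_swap <- s_swap * exp(g * (a - 0.44))

      ## --- log range and log sd, separate scalar walks ---
      for (h in 1:2) {
        lr_new <- lrange + if (h == 1) s_hyp[1] * stats::rnorm(1) else 0
        ls_new <- lsd + if (h == 2) s_hyp[2] * stats::rnorm(1) else 0
        cs <- upd_cov(lr_new, ls_new)
        if (!is.null(cs)) {
          w <- backsolve(cs$ch, u, transpose = TRUE)
          quad_new <- sum(w^2)
          dlp <- (-0.5 * cs$logdet - 0.5 * quad_new +
                    priors$range$logd(exp(lr_new)) + lr_new +
                    priors$sd$logd(exp(ls_new)) + ls_new) -
                 (-0.5 * logdet - 0.5 * quad +
                    priors$range$logd(exp(lrange)) + lrange +
                    priors$sd$logd(exp(lsd)) + lsd)
          a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
        } else a <- 0
        if (stats::runif(1) < a) {
          lrange <- lr_new; lsd <- ls_new
          Q <- cs$Q; logdet <- cs$logdet; quad <- quad_new
          Qu <- drop(Q %*% u); rowQ <- rowSums(Q); sumQ <- sum(rowQ)
          acc["hyper"] <- acc["hyper"] + 0.5
        }
        if (adapting) s_hyp[h] <- s_hyp[h] * exp(g * (a - 0.44))
      }
    }

    ## --- NB size ---
    if (family == "negbin") {
      lsize_new <- lsize + s_size * stats::rnorm(1)
      ll_new <- .ll_sum(y, eta, family, exp(lsize_new), zi)
      dlp <- ll_new - cur_ll +
        .log_prior_size(lsize_new, priors$size_lambda) -
        .log_prior_size(lsize, priors$size_lambda)
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) {
        lsize <- lsize_new; size <- exp(lsize); cur_ll <- ll_new
        acc["size"] <- acc["size"] + 1
      }
      if (adapting) s_size <- s_size * exp(g * (a - 0.44))
    }

    ## --- ZIP zero-inflation ---
    if (family == "zip") {
      lzi_new <- lzi + s_zi * stats::rnorm(1)
      zi_new <- stats::plogis(lzi_new)
      ll_new <- .ll_sum(y, eta, family, size, zi_new)
      dlp <- ll_new - cur_ll +
        stats::dbeta(zi_new, priors$zi_shape1, priors$zi_shape2, log = TRUE) +
        log(zi_new * (1 - zi_new)) -
        stats::dbeta(zi, priors$zi_shape1, priors$zi_shape2, log = TRUE) -
        log(zi * (1 - zi))
      a <- if (is.finite(dlp)) min(1, exp(dlp)) else 0
      if (stats::runif(1) < a) {
        lzi <- lzi_new; zi <- zi_new; cur_ll <- ll_new
        acc["zi"] <- acc["zi"] + 1
      }
      if (adapting) s_zi <- s_zi * exp(g * (a - 0.44))
    }

    # guard against incremental drift in the cached log-likelihood
    if (it %% 500 == 0) cur_ll <- .ll_sum(y, eta, family, size, zi)

    ## --- storage ---
    if (it > warmup && (it - warmup - 1L) %% thin == 0L) {
      k <- k + 1L
      keep_beta[k, ] <- beta
      if (spatial) keep_u[k, ] <- u
      keep_range[k] <- exp(lrange); keep_sd[k] <- exp(lsd)
      keep_size[k] <- size; keep_zi[k] <- zi
      keep_dev[k] <- -2 * .ll_sum(y, eta, family, size, zi)
      keep_pearson[k] <- .pearson_stat(y, eta, family, size, zi, p)
      eta_sum <- eta_sum + eta
    }
  }

  list(beta = keep_beta[seq_len(k), , drop = FALSE],
       u = if (spatial) keep_u[seq_len(k), , drop = FALSE],
       range = keep_range[seq_len(k)], sd = keep_sd[seq_len(k)],
       size = keep_size[seq_len(k)], zi = keep_zi[seq_len(k)],
       deviance = keep_dev[seq_len(k)], pearson = keep_pearson[seq_len(k)],
       eta_mean = eta_sum / k,
       accept = acc / n_iter, n_kept = k)
}

# split-Rhat over a draws-by-chains matrix
.split_rhat <- function(x) {
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(mu)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from pooled autocorrelations
.ess <- function(x) {
  nch <- ncol(x); n <- nrow(x)
  rho <- rep(0, min(100, n - 2))
  for (j in seq_len(nch)) {
    a <- stats::acf(x[, j], lag.max = length(rho), plot = FALSE,
                    demean = TRUE)$acf[-1]
    rho <- rho + a / nch
  }
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  max(1, n * nch / (1 + 2 * sum(rho)))
}
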