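test_that("input contracts are enforced before any sampling", {
  y <- rpois(30, 2); X <- cbind(x = rnorm(30))
  expect_error(fit_count_model(c(-1L, y[-1]), X, spatial = FALSE),
               "non-negative")
  expect_error(fit_count_model(y, X, spatial = FALSE, chains = 1),
               "2 chains")
  expect_error(fit_count_model(y, cbind(X, x2 = X[, 1]), spatial = FALSE),
               "rank deficient")
  expect_error(fit_count_model(y, X, spatial = TRUE), "requires")
  coords1 <- data.frame(site_id = c("a", "b"), easting_km = c(0, 1),
                        northing_km = c(0, 1))
  expect_error(
    fit_count_model(y, X, sites = rep(c("a", "b"), 15), coords = coords1),
    "at least 3 distinct sites")
})

test_that("non-spatial Poisson posterior matches the ML oracle", {
  po <- poisson_oracle()
  # posterior mode against the independent IRLS fit, to 3 decimals
  mode <- posterior_mode(po$fit)
  expect_equal(unname(mode), unname(coef(po$glm)), tolerance = 5e-4)
  # posterior mean concentrates on the same solution
  expect_equal(unname(colMeans(po$fit$draws$beta)), unname(coef(po$glm)),
               tolerance = 5e-3)
})

test_that("Pearson dispersion is ~1 for a correctly specified Poisson fit", {
  po <- poisson_oracle()
  o <- overdispersion_stat(po$fit)
  expect_equal(o$estimate, 1, tolerance = 0.05)
  expect_lt(o$lower, o$estimate); expect_gt(o$upper, o$estimate)
})

test_that("Poisson fits to overdispersed data show dispersion >> 1", {
  set.seed(21)
  n <- 800
  X <- cbind(x = rnorm(n))
  y <- rnbinom(n, size = 1, mu = exp(1 + 0.4 * X[, 1]))
  f <- fit_count_model(y, X, family = "poisson", spatial = FALSE,
                       chains = 2, iter = 1200, seed = 22,
                       on_nonconvergence = "warn")
  expect_gt(overdispersion_stat(f)$estimate, 2)
})

test_that("a degenerate posterior has pD = 0 and DIC = D(theta-hat)", {
  f <- degenerate_fit()
  d <- dic(f)
  expect_equal(d$pd, 0, tolerance = 1e-10)
  expect_equal(d$dic, d$d_hat, tolerance = 1e-10)
})

test_that("ZIP fits recover the zero-inflation probability", {
  set.seed(23)
  n <- 1500
  X <- cbind(x = rnorm(n))
  y <- ifelse(runif(n) < 0.4, 0L, rpois(n, exp(1.1 + 0.3 * X[, 1])))
  f <- fit_count_model(y, X, family = "zip", spatial = FALSE,
                       chains = 2, iter = 1500, seed = 24,
                       on_nonconvergence = "warn")
  q <- quantile(f$draws$zi, c(0.025, 0.975))
  expect_lt(q[1], 0.4); expect_gt(q[2], 0.4)
  expect_equal(mean(f$draws$zi), 0.4, tolerance = 0.05)
})

test_that("spatial and non-spatial fits agree when the field is absent", {
  # data generated without any spatial effect
  cfg <- generator_config(c("(Intercept)" = 1.2, x = 0.4), family = "negbin",
                          true_sd = 0, nb_size = 1, seed = 30)
  lay <- generate_sites(15, mean_obs = 60, seed = 31)
  s <- simulate_counts(lay, cfg)
  f_sp <- fit_count_model(s$data$count, s$design, sites = s$data$site_id,
                          coords = lay, family = "negbin", spatial = TRUE,
                          chains = 2, iter = 1500, seed = 32,
                          on_nonconvergence = "warn")
  f_ns <- fit_count_model(s$data$count, s$design, family = "negbin",
                          spatial = FALSE, chains = 2, iter = 1500, seed = 33,
                          on_nonconvergence = "warn")
  expect_equal(colMeans(f_sp$draws$beta)[-1], colMeans(f_ns$draws$beta)[-1],
               tolerance = 0.05)
  # the PC prior shrinks the unneeded field toward zero
  expect_lt(median(f_sp$draws$sd), 0.3)
})

test_that("identical specifications give equal DIC within Monte-Carlo error", {
  s <- small_sim()
  cm <- compare_models(
    list(list(family = "negbin", spatial = FALSE, label = "m1"),
         list(family = "negbin", spatial = FALSE, label = "m2")),
    y = s$data$count, X = s$design, chains = 2, iter = 1200, seed = 40,
    on_nonconvergence = "warn")
  expect_lt(abs(diff(cm$table$dic)), 5)
})

test_that("coefficient importance calls have roughly nominal error rates", {
  # a null coefficient should be flagged unimportant in most replicates,
  # a strong one always important
  set.seed(50)
  flags_null <- flags_strong <- logical(12)
  for (k in 1:12) {
    n <- 600
    X <- cbind(x_null = rnorm(n), x_strong = rnorm(n))
    y <- rnbinom(n, size = 1, mu = exp(1 + 0.5 * X[, "x_strong"]))
    f <- fit_count_model(y, X, family = "negbin", spatial = FALSE,
                         chains = 2, iter = 1000, seed = 50 + k,
                         on_nonconvergence = "warn")
    cs <- coef_summary(f)
    flags_null[k] <- cs$important[cs$term == "x_null"]
    flags_strong[k] <- cs$important[cs$term == "x_strong"]
  }
  expect_lte(sum(flags_null), 2)     # ~5% nominal false-positive rate
  expect_true(all(flags_strong))
})

test_that("convergence failures are loud and carry the parameter names", {
  s <- small_sim()
  expect_error(
    fit_count_model(s$data$count, s$design, sites = s$data$site_id,
                    coords = s$layout, family = "negbin", spatial = TRUE,
                    chains = 2, iter = 450, warmup = 200, seed = 60),
    "Rhat|converge")
})
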