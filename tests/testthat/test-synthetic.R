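test_that("site layouts respect counts, extent and the observation floor", {
  lay <- generate_sites(51, extent_km = 11.3, seed = 1)
  expect_equal(nrow(lay), 51)
  expect_true(all(lay$easting_km >= 0 & lay$easting_km <= 11.3))
  expect_true(all(lay$n_obs >= 30))
  expect_equal(mean(lay$n_obs), 100, tolerance = 0.05)
  expect_false(any(duplicated(lay$site_id)))
  # two sites in a unit square: distance in (0, sqrt(2)]
  l2 <- generate_sites(2, extent_km = 1, seed = 2)
  d <- site_distances(l2[, 2:3])[1, 2]
  expect_gt(d, 0); expect_lte(d, sqrt(2))
  expect_error(generate_sites(1), "at least 2 sites")
})

test_that("layouts and datasets are bit-identical under a fixed seed", {
  expect_identical(generate_sites(20, seed = 7), generate_sites(20, seed = 7))
  cfg <- scenario_aegypti(seed = 5)
  s1 <- simulate_scenario(cfg, n_sites = 10, mean_obs = 35)
  s2 <- simulate_scenario(cfg, n_sites = 10, mean_obs = 35)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$u, s2$u)
})

test_that("weather series cover the span and hit the humidity correlation", {
  w <- generate_weather("2017-01-01", "2017-12-31", seed = 4)
  expect_equal(nrow(w), 365)
  expect_false(anyNA(w))
  rho <- cor(w$temperature, w$humidity, method = "spearman")
  expect_lt(abs(rho - 0.61), 0.15)
  w0 <- generate_weather("2017-01-01", "2017-12-31", humid_temp_cor = 0,
                         seed = 4)
  expect_lt(abs(cor(w0$temperature, w0$humidity, method = "spearman")), 0.2)
  expect_error(generate_weather("2017-01-01", "2017-01-10"), "14 days")
})

test_that("counts are iid Poisson when the field and slopes vanish", {
  cfg <- generator_config(c("(Intercept)" = 1.2), family = "poisson",
                          true_sd = 0, seed = 8)
  lay <- generate_sites(10, mean_obs = 400, seed = 9)
  s <- simulate_counts(lay, cfg)
  expect_equal(mean(s$data$count), exp(1.2), tolerance = 0.03)
  expect_equal(var(s$data$count), exp(1.2), tolerance = 0.06)
})

test_that("negative binomial counts reach the Poisson limit at large size", {
  cfg <- generator_config(c("(Intercept)" = 1.0), family = "negbin",
                          nb_size = 1e6, true_sd = 0, seed = 10)
  lay <- generate_sites(10, mean_obs = 400, seed = 11)
  s <- simulate_counts(lay, cfg)
  expect_equal(var(s$data$count) / mean(s$data$count), 1, tolerance = 0.08)
})

test_that("the rare-species scenario is dominated by zeros", {
  s <- simulate_scenario(scenario_albopictus(seed = 6), n_sites = 30,
                         mean_obs = 60)
  expect_gt(mean(s$data$count == 0), 0.5)
  # and the abundant scenario is not
  s2 <- simulate_scenario(scenario_aegypti(seed = 6), n_sites = 30,
                          mean_obs = 60)
  expect_lt(mean(s2$data$count == 0), 0.4)
})

test_that("replicate spatial fields reproduce the Matern covariance", {
  lay <- generate_sites(12, extent_km = 4, mean_obs = 30, seed = 20)
  D <- site_distances(lay[, 2:3])
  nrep <- 600
  U <- sapply(seq_len(nrep), function(k) {
    cfg <- generator_config(c("(Intercept)" = 0), family = "poisson",
                            true_range_km = 1.2, true_sd = 0.8, seed = k)
    simulate_counts(lay, cfg)$u
  })
  emp <- tcrossprod(U) / nrep   # mean-zero field: raw second moments
  theo <- matern_cov(D, 1.2, 0.8)
  # entrywise agreement within Monte-Carlo error (sd of a product moment
  # ~ sigma^2 sqrt((1 + rho^2)/n) <= 0.037 here); allow 4 sd
  expect_lt(max(abs(emp - theo)), 4 * 0.8^2 * sqrt(2 / nrep))
})

test_that("a missing design column is reported by name", {
  cfg <- scenario_aegypti(seed = 1)
  lay <- generate_sites(5, mean_obs = 30, seed = 1)
  X <- matrix(0, sum(lay$n_obs), 1, dimnames = list(NULL, "trees"))
  expect_error(simulate_counts(lay, cfg, design = X), "humidity")
})
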