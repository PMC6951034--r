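test_that("kriging is exact at the sites and reverts to the prior far away", {
  f <- small_fit()
  nd <- length(f$draws$range)
  at_sites <- interpolate_field(f, f$coords, n_draws = nd, seed = 1)
  expect_equal(at_sites$u_mean, unname(colMeans(f$draws$u)), tolerance = 1e-4)
  far <- data.frame(easting_km = 60, northing_km = 60)
  out <- interpolate_field(f, far, n_draws = nd, seed = 2)
  expect_equal(out$u_mean, 0, tolerance = 0.02)
  expect_equal(out$u_sd, sqrt(mean(f$draws$sd^2)), tolerance = 0.02)
})

test_that("predictive sd grows along a ray leaving the site layout", {
  f <- small_fit()
  # marching away from the layout's eastern edge, every site recedes, so
  # the per-cell predictive sd is non-decreasing and saturates at the
  # field's marginal sd
  start <- max(f$coords$easting_km) + 0.2
  ray <- data.frame(easting_km = start + seq(0, 30, by = 1.5),
                    northing_km = mean(f$coords$northing_km))
  out <- interpolate_field(f, ray, n_draws = 100, seed = 3)
  # pooling over posterior draws adds O(1e-3) wobble around the per-draw
  # monotone profile as the kriging-mean spread decays to zero
  expect_true(all(diff(out$u_sd) > -5e-3))
  expect_lt(out$u_sd[1], out$u_sd[nrow(out)])
})

test_that("grid units far from any site trigger the unit-check warning", {
  f <- small_fit()
  grid_m <- data.frame(easting_km = 5e5, northing_km = 5e5)  # metre-like
  expect_warning(interpolate_field(f, grid_m, n_draws = 20, seed = 4),
                 "km")
})

test_that("prediction at the covariate mean equals the intercept rate", {
  f <- small_fit_nonspatial()
  terms <- setdiff(colnames(f$X), "(Intercept)")
  g <- data.frame(easting_km = 1, northing_km = 1, week = 1)
  for (v in terms) g[[v]] <- 0
  ps <- predict_weekly(f, g, n_draws = length(f$draws$deviance), seed = 5)
  b0 <- mean(exp(f$draws$beta[, 1]))
  expect_equal(ps$cells$mean, b0, tolerance = 0.1)
  expect_true(ps$cells$lower <= ps$cells$mean &
                ps$cells$mean <= ps$cells$upper)
})

test_that("increasing a positive-coefficient covariate raises predictions", {
  f <- small_fit_nonspatial()
  cs <- coef_summary(f)
  v <- "humidity"   # strongly positive in the generating truth
  expect_gt(cs$mean[cs$term == v], 0)
  terms <- setdiff(colnames(f$X), "(Intercept)")
  g <- data.frame(easting_km = c(1, 1), northing_km = c(1, 1), week = c(1, 1))
  for (t in terms) g[[t]] <- 0
  g[[v]] <- c(-1, 1)
  ps <- predict_weekly(f, g, n_draws = 500, seed = 6)
  expect_gt(ps$cells$mean[2], ps$cells$mean[1])
})

test_that("cells with identical covariates and positions predict alike", {
  f <- small_fit()
  terms <- setdiff(colnames(f$X), "(Intercept)")
  g <- data.frame(easting_km = c(3, 3), northing_km = c(4, 4),
                  week = c(1, 1))
  for (t in terms) g[[t]] <- 0.5
  ps <- predict_weekly(f, g, n_draws = 500, seed = 7)
  expect_equal(ps$cells$mean[1], ps$cells$mean[2], tolerance = 0.15)
})

test_that("missing model terms are reported by name", {
  f <- small_fit_nonspatial()
  g <- data.frame(easting_km = 1, northing_km = 1, week = 1)
  expect_error(predict_weekly(f, g), "humidity")
})

test_that("weekly grid covariates use training constants and daily lags", {
  w <- generate_weather("2017-01-01", "2017-03-31", seed = 8)
  # training scaling: humidity on its natural scale
  scaling <- data.frame(column = c("humidity", "trees"),
                        center = c(2200, 0.2), scale = c(600, 0.1))
  grid <- data.frame(easting_km = c(0, 1), northing_km = c(0, 1),
                     trees = c(0.2, 0.3))
  gc <- weekly_grid_covariates(grid, w[, c("date", "humidity")], scaling,
                               terms = c("humidity", "trees"), weeks = 4:6)
  expect_equal(sort(unique(gc$week)), 4:6)
  # static covariate standardized with the training constants
  expect_equal(gc$trees[gc$easting_km == 0][1], 0)
  expect_equal(gc$trees[gc$easting_km == 1][1], 1)
  # weather is shared across cells within a week
  for (wk in 4:6)
    expect_equal(length(unique(gc$humidity[gc$week == wk])), 1)
})
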