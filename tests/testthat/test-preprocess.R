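test_that("standardization centers, scales, inverts and is idempotent", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$x, c(-1, 0, 1))
  expect_equal(s$center, 2); expect_equal(s$scale, 1)
  # round trip
  x <- rnorm(50, 7, 3)
  s2 <- standardize(x)
  expect_equal(destandardize(s2$x, s2$center, s2$scale), x, tolerance = 1e-12)
  # re-standardizing an already standardized column changes nothing
  s3 <- standardize(s2$x)
  expect_equal(s3$x, s2$x, tolerance = 1e-12)
  expect_error(standardize(c(5, 5, 5)), "zero variance")
  # frozen constants are honoured
  s4 <- standardize(c(10, 20), center = 0, scale = 10)
  expect_equal(s4$x, c(1, 2))
})

test_that("lag columns pick the daily value 0, 7 and 14 days before", {
  dates <- seq(as.Date("2017-01-01"), as.Date("2017-06-30"), by = "day")
  series <- data.frame(date = dates, v = seq_along(dates))
  lag <- build_lags(series, as.Date("2017-04-10"))
  expect_equal(lag$v_lag0, 100)   # day-of-year index
  expect_equal(lag$v_lag1, 93)
  expect_equal(lag$v_lag2, 86)
  # lag 0 equals the same-day series exactly
  obs <- sample(dates[20:100], 30)
  l <- build_lags(series, obs)
  expect_equal(l$v_lag0, series$v[match(obs, dates)])
  # constant series: all lags identical
  cs <- data.frame(date = dates, v = rep(2.5, length(dates)))
  lc <- build_lags(cs, dates[30:40])
  expect_true(all(lc$v_lag0 == lc$v_lag1 & lc$v_lag1 == lc$v_lag2))
  # a date before the series start is named in the error
  expect_error(build_lags(series, dates[3]), "2016-12-27")
})

test_that("correlated pairs are flagged with their Spearman rho", {
  set.seed(1)
  a <- rnorm(200)
  d <- data.frame(a = a, b = -a, c = rnorm(200))
  fl <- flag_correlated_pairs(d)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$a, "a"); expect_equal(fl$b, "b")
  expect_equal(fl$rho, -1)
  # independent standard normals at large n: empty with high probability
  set.seed(2)
  d2 <- as.data.frame(matrix(rnorm(4000), 1000, 4))
  expect_equal(nrow(flag_correlated_pairs(d2)), 0)
})

test_that("the generator's weather pair is flagged at the default threshold", {
  w <- generate_weather("2017-01-01", "2017-12-31", seed = 4)
  lay <- generate_sites(6, mean_obs = 60, seed = 5)
  obs <- sample(seq(as.Date("2017-01-20"), as.Date("2017-12-31"), by = "day"),
                sum(lay$n_obs), replace = TRUE)
  lags <- build_lags(w[, c("date", "temperature", "humidity")], obs)
  fl <- flag_correlated_pairs(lags[, c("temperature_lag0", "humidity_lag0")])
  expect_equal(nrow(fl), 1)
  expect_gt(fl$rho, 0.4)
})

test_that("interaction columns are products and are not re-standardized", {
  d <- data.frame(a = c(-1, 0, 1), b = c(1, 1, 1))
  d2 <- add_interaction(d, "a", "b")
  expect_equal(d2[["a:b"]], c(-1, 0, 1))
  expect_error(add_interaction(d2, "a", "b"), "duplicate")
  expect_error(add_interaction(d, "a", "zz"), "zz")
  # mean of the product need not be 0: contract says leave it alone
  set.seed(3)
  d3 <- data.frame(a = rnorm(100) + 1, b = rnorm(100) + 1)
  sd3 <- standardize_design(d3)$design
  d4 <- add_interaction(sd3, "a", "b")
  expect_equal(d4[["a:b"]], sd3$a * sd3$b)
  # zero rows stay zero
  d5 <- add_interaction(data.frame(a = c(0, 0), b = c(3, 4)), "a", "b")
  expect_equal(d5[["a:b"]], c(0, 0))
})

test_that("design standardization freezes and reapplies training constants", {
  set.seed(4)
  train <- data.frame(t1 = rnorm(60, 20, 5), t2 = rnorm(60, 1000, 100))
  sd_out <- standardize_design(train)
  expect_equal(unname(colMeans(sd_out$design)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sapply(sd_out$design, sd)), c(1, 1), tolerance = 1e-12)
  new <- data.frame(t1 = c(20, 25), t2 = c(1000, 1100))
  tr <- standardize_design(new, scaling = sd_out$scaling)$design
  i <- match("t1", sd_out$scaling$column)
  expect_equal(tr$t1[1], (20 - sd_out$scaling$center[i]) / sd_out$scaling$scale[i])
})

test_that("design round-trips through CSV with its scaling sidecar", {
  set.seed(5)
  d <- data.frame(a = rnorm(10), b = rnorm(10))
  sc <- standardize_design(d)
  path <- file.path(tempdir(), "design_test.csv")
  write_design(sc$design, sc$scaling, path)
  back <- read_design(path)
  expect_equal(back$design, sc$design, tolerance = 1e-12)
  expect_equal(back$scaling$center, sc$scaling$center, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
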