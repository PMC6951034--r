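test_that("Poisson log-likelihood matches the closed form", {
  expect_equal(exp(count_loglik(2L, 2, "poisson")), exp(-2) * 2^2 / 2,
               tolerance = 1e-12)
})

test_that("ZIP with zero inflation 0 is exactly Poisson", {
  y <- c(0L, 1L, 5L, 0L, 3L)
  mu <- c(0.5, 1, 4, 9, 2)
  expect_equal(count_loglik(y, mu, "zip", zi = 0),
               count_loglik(y, mu, "poisson"), tolerance = 1e-12)
})

test_that("negative binomial approaches Poisson as size grows", {
  y <- 0:15
  mu <- rep(3.2, length(y))
  expect_equal(count_loglik(y, mu, "negbin", size = 1e6),
               count_loglik(y, mu, "poisson"), tolerance = 1e-4)
})

test_that("pmfs sum to one over a truncated support", {
  k <- 0:400
  for (args in list(list(family = "poisson"),
                    list(family = "negbin", size = 0.7),
                    list(family = "zip", zi = 0.3))) {
    ll <- do.call(count_loglik,
                  c(list(y = k, mu = rep(5, length(k))), args))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-8)
  }
})

test_that("family mean and variance match simulation moments", {
  set.seed(4)
  n <- 2e5
  y <- count_simulate(n, rep(3, n), "zip", zi = 0.4)
  expect_equal(mean(y), count_mean(3, "zip", zi = 0.4), tolerance = 0.02)
  expect_equal(var(y), count_variance(3, "zip", zi = 0.4), tolerance = 0.02)
  y2 <- count_simulate(n, rep(3, n), "negbin", size = 1.5)
  expect_equal(var(y2), count_variance(3, "negbin", size = 1.5),
               tolerance = 0.02)
})

test_that("invalid counts and means are rejected", {
  expect_error(count_loglik(-1L, 1, "poisson"), "non-negative")
  expect_error(count_loglik(1.5, 1, "poisson"), "integers")
  expect_error(count_loglik(c(1L, 2L), c(1, -3), "poisson"), "row 2")
})
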