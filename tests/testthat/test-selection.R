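test_that("a strong predictor is included and nulls are not", {
  set.seed(42)
  n <- 2000
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- rnbinom(n, size = 1, mu = exp(0.5 + 0.5 * X[, 1]))
  r <- spike_slab_select(y, X, n_iter = 2500, burn_in = 500, seed = 7)
  ip <- setNames(r$ranking$inclusion_probability, r$ranking$term)
  expect_gt(ip["v1"], 0.9)
  expect_lt(median(ip[paste0("v", 2:10)]), 0.3)
  expect_equal(r$ranking$term[1], "v1")
  # scaled effect close to the generating coefficient
  expect_equal(r$ranking$scaled_effect[r$ranking$term == "v1"], 0.5,
               tolerance = 0.1)
})

test_that("pure-noise designs do not produce confident inclusions", {
  set.seed(43)
  n <- 800
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rnbinom(n, size = 1, mu = exp(0.8))
  r <- spike_slab_select(y, X, n_iter = 2000, burn_in = 500, seed = 8)
  expect_lt(max(r$ranking$inclusion_probability), 0.9)
})

test_that("degenerate candidate designs are rejected, never silently used", {
  set.seed(44)
  y <- rpois(50, 2)
  X <- cbind(a = rnorm(50), b = rep(0, 50))
  expect_error(spike_slab_select(y, X), "constant")
  X2 <- cbind(a = rnorm(50))
  X2 <- cbind(X2, a2 = X2[, 1])
  expect_error(spike_slab_select(y, X2), "rank deficient")
  expect_error(spike_slab_select(c(-1L, y[-1]), X[, 1, drop = FALSE]),
               "non-negative")
})

test_that("Gaussian-likelihood Gibbs matches brute-force enumeration", {
  # independent oracle: integrate beta out analytically per gamma
  # configuration and enumerate all 2^p models
  set.seed(5)
  n <- 40; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 0.3 + 0.8 * X[, 1] + rnorm(n)
  prior <- spike_slab_prior()
  Xf <- cbind(1, X)
  lml <- function(gam) {
    v <- c(100, ifelse(gam == 1, prior$slab_sd^2, prior$spike_sd^2))
    S <- diag(n) + Xf %*% (v * t(Xf))
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2) +
      sum(dbinom(gam, 1, prior$w, log = TRUE))
  }
  gs <- as.matrix(expand.grid(rep(list(0:1), p)))
  lp <- apply(gs, 1, lml)
  wts <- exp(lp - max(lp)); wts <- wts / sum(wts)
  oracle <- colSums(gs * wts)
  r <- spike_slab_select(y, X, prior, n_iter = 22000, burn_in = 2000,
                         family = "gaussian", sigma = 1, seed = 2)
  got <- r$ranking$inclusion_probability[match(paste0("x", 1:p),
                                               r$ranking$term)]
  expect_equal(got, unname(oracle), tolerance = 0.03)
})

test_that("inclusion probabilities are stable under column reordering", {
  set.seed(46)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnbinom(n, size = 1, mu = exp(0.5 + 0.6 * X[, 2]))
  r1 <- spike_slab_select(y, X, n_iter = 2000, burn_in = 500, seed = 9)
  r2 <- spike_slab_select(y, X[, 4:1], n_iter = 2000, burn_in = 500, seed = 9)
  ip1 <- setNames(r1$ranking$inclusion_probability, r1$ranking$term)
  ip2 <- setNames(r2$ranking$inclusion_probability, r2$ranking$term)
  expect_equal(ip1[paste0("v", 1:4)], ip2[paste0("v", 1:4)], tolerance = 0.1)
})

fake_selection <- function(terms, ip, eff) {
  structure(list(ranking = data.frame(term = terms,
                                      inclusion_probability = ip,
                                      scaled_effect = eff,
                                      rank = seq_along(terms))),
            class = "selection_result")
}

test_that("per-weather-group only the largest-effect lag survives", {
  r <- fake_selection(
    c("temp_lag0", "temp_lag1", "temp_lag2", "a", "b", "c", "d", "e"),
    c(0.9, 0.95, 0.85, 0.99, 0.98, 0.97, 0.96, 0.8),
    c(0.1, -0.3, 0.2, 0.5, 0.4, 0.3, 0.25, 0.2))
  chosen <- choose_top_six(r, weather_groups =
    list(temp = c("temp_lag0", "temp_lag1", "temp_lag2")))
  expect_true("temp_lag1" %in% chosen)
  expect_false(any(c("temp_lag0", "temp_lag2") %in% chosen))
  expect_length(chosen, 6)
})

test_that("short candidate lists are returned whole with a warning", {
  r <- fake_selection(c("a", "b", "c"), c(0.9, 0.8, 0.7), c(0.3, 0.2, 0.1))
  expect_warning(chosen <- choose_top_six(r), "fewer than 6")
  expect_equal(sort(chosen), c("a", "b", "c"))
})

test_that("effect-size ties at the final slot break alphabetically", {
  r <- fake_selection(letters[1:7], rep(0.9, 7),
                      c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.4))
  expect_message(chosen <- choose_top_six(r), "alphabet")
  expect_equal(chosen[6], "f")   # f beats g on the tie
})
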