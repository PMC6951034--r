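# Kriging interpolation of the spatial field and weekly gridded prediction.

#' Interpolate the spatial random effect over a grid
#'
#' For each posterior draw, computes the conditional (kriging) mean of the
#' Matern field at the grid cells given the site-level field values under
#' that draw's (range, sd), and pools draws into a predictive mean and sd per
#' cell. At a cell coincident with a site the interpolation is exact; far
#' from all sites the mean reverts to 0 and the sd to the field's marginal
#' sd.
#'
#' @param fit a spatial `trap_fit`.
#' @param grid data frame with `easting_km`, `northing_km` (same projected
#'   coordinate system as the fit).
#' @param n_draws number of posterior draws used; default 200.
#' @param seed seed for the draw subsample.
#' @return `grid` with added columns `u_mean`, `u_sd`.
#' @export
interpolate_field <- function(fit, grid, n_draws = 200, seed = 1L) {
  stopifnot(inherits(fit, "trap_fit"))
  if (!fit$spatial) stop("fit has no spatial effect to interpolate")
  grid <- as.data.frame(grid)
  stopifnot(all(c("easting_km", "northing_km") %in% names(grid)))
  set.seed(seed)
  sxy <- as.matrix(fit$coords[, c("easting_km", "northing_km")])
  gxy <- as.matrix(grid[, c("easting_km", "northing_km")])
  cross <- .cross_dist(gxy, sxy)
  med_range <- stats::median(fit$draws$range)
  if (min(cross) > 100 * med_range)
    warning("all grid-site distances exceed 100x the posterior range; ",
            "are the grid coordinates in km?")
  nd <- length(fit$draws$range)
  take <- sample.int(nd, min(n_draws, nd))
  m1 <- m2 <- v <- numeric(nrow(grid))
  for (i in take) {
    rho <- fit$draws$range[i]; sg <- fit$draws$sd[i]
    Css <- matern_cov(fit$D, rho, sg)
    Cgs <- .matern_k(cross, rho, sg)
    ch <- chol(Css)
    A <- Cgs %*% chol2inv(ch)                 # kriging weights
    cm <- drop(A %*% fit$draws$u[i, ])
    cv <- pmax(0, sg^2 - rowSums(A * Cgs))
    m1 <- m1 + cm; m2 <- m2 + cm^2; v <- v + cv
  }
  n <- length(take)
  grid$u_mean <- m1 / n
  grid$u_sd <- sqrt(pmax(0, v / n + m2 / n - (m1 / n)^2))
  grid
}

.cross_dist <- function(a, b) {
  ra <- rowSums(a^2); rb <- rowSums(b^2)
  d2 <- outer(ra, rb, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Weekly gridded count predictions
#'
#' For each posterior draw, grid cell and week, forms the linear predictor
#' \eqn{\log\mu = x^T\beta + u(\mathrm{cell})} (the cell field drawn from its
#' per-cell conditional distribution given the sites) and draws a predicted
#' trap count from the fitted family, assuming one trap-night per cell-week.
#' Returns per-cell-week posterior mean counts with 95% intervals and the
#' city-wide weekly series both summed and averaged over cells.
#'
#' @param fit a `trap_fit`.
#' @param grid_covariates data frame with `easting_km`, `northing_km`,
#'   `week`, and one column per model term (already transformed with the
#'   *training* standardization constants; interaction terms computed from
#'   the standardized parents).
#' @param n_draws posterior draws used; default 200.
#' @param seed integer seed.
#' @return object of class `prediction_surface`: `$cells` (per cell-week
#'   mean/lower/upper plus the interpolated field), `$weekly` (per-week
#'   `sum_mean`, `sum_lower`, `sum_upper`, `mean_mean`, ...).
#' @export
predict_weekly <- function(fit, grid_covariates, n_draws = 200, seed = 1L) {
  stopifnot(inherits(fit, "trap_fit"))
  gc <- as.data.frame(grid_covariates)
  stopifnot(all(c("easting_km", "northing_km", "week") %in% names(gc)))
  terms <- setdiff(colnames(fit$X), "(Intercept)")
  miss <- setdiff(terms, names(gc))
  if (length(miss)) stop("missing model term(s): ", paste(miss, collapse = ", "))
  set.seed(seed)
  nd <- length(fit$draws$deviance)
  take <- sample.int(nd, min(n_draws, nd), replace = nd < n_draws)
  Xg <- cbind("(Intercept)" = 1, as.matrix(gc[, terms, drop = FALSE]))

  # unique cells and their conditional field distribution per draw
  cell_key <- paste(gc$easting_km, gc$northing_km)
  cells <- !duplicated(cell_key)
  cxy <- as.matrix(gc[cells, c("easting_km", "northing_km")])
  cell_of <- match(cell_key, cell_key[cells])
  nG <- nrow(gc)
  pred <- matrix(0, nG, length(take))
  for (j in seq_along(take)) {
    i <- take[j]
    if (fit$spatial) {
      rho <- fit$draws$range[i]; sg <- fit$draws$sd[i]
      Css <- matern_cov(fit$D, rho, sg)
      Cgs <- .matern_k(.cross_dist(cxy, as.matrix(
        fit$coords[, c("easting_km", "northing_km")])), rho, sg)
      A <- Cgs %*% chol2inv(chol(Css))
      cm <- drop(A %*% fit$draws$u[i, ])
      cv <- pmax(0, sg^2 - rowSums(A * Cgs))
      u_cell <- stats::rnorm(nrow(cxy), cm, sqrt(cv))
      u <- u_cell[cell_of]
    } else u <- 0
    eta <- drop(Xg %*% fit$draws$beta[i, ]) + u
    pred[, j] <- count_simulate(nG, exp(eta), fit$family,
                                size = fit$draws$size[i],
                                zi = fit$draws$zi[i])
  }
  q <- t(apply(pred, 1, stats::quantile, c(0.025, 0.975), names = FALSE))
  cells_out <- data.frame(
    easting_km = gc$easting_km, northing_km = gc$northing_km,
    week = gc$week,
    mean = rowMeans(pred), lower = q[, 1], upper = q[, 2]
  )
  wk <- sort(unique(gc$week))
  wsum <- sapply(wk, function(w) {
    tot <- colSums(pred[gc$week == w, , drop = FALSE])
    c(mean(tot), stats::quantile(tot, c(0.025, 0.975), names = FALSE))
  })
  wmean <- sapply(wk, function(w) {
    m <- colMeans(pred[gc$week == w, , drop = FALSE])
    c(mean(m), stats::quantile(m, c(0.025, 0.975), names = FALSE))
  })
  weekly <- data.frame(week = wk,
                       sum_mean = wsum[1, ], sum_lower = wsum[2, ],
                       sum_upper = wsum[3, ],
                       mean_mean = wmean[1, ], mean_lower = wmean[2, ],
                       mean_upper = wmean[3, ])
  structure(list(cells = cells_out, weekly = weekly),
            class = "prediction_surface")
}

#' Build weekly grid covariates from daily weather and static cell covariates
#'
#' Applies the daily lag rule (value 0/7/14 days before a week's reference
#' day), averages each lag column over the days of each ISO week, transforms
#' with the training standardization constants and recomputes interaction
#' columns as products of the standardized parents.
#'
#' @param grid data frame of cells: `easting_km`, `northing_km`, plus static
#'   covariate columns in natural units.
#' @param weather daily weather series (see [generate_weather()]).
#' @param scaling training scaling table from [standardize_design()].
#' @param terms model terms to materialize (interaction names `"A:B"`).
#' @param weeks integer ISO-ordinal weeks to cover; default all complete
#'   weeks with full lag support.
#' @return data frame with one row per cell-week holding all `terms`.
#' @export
weekly_grid_covariates <- function(grid, weather, scaling, terms,
                                   weeks = NULL) {
  grid <- as.data.frame(grid)
  dates <- as.Date(weather$date)
  wk_all <- as.integer(format(dates, "%V"))
  ok <- dates >= min(dates) + 14
  if (is.null(weeks)) weeks <- sort(unique(wk_all[ok]))
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  std1 <- function(v, x) {
    i <- match(v, scaling$column)
    if (is.na(i)) stop("no training scaling for term: ", v)
    (x - scaling$center[i]) / scaling$scale[i]
  }
  rows <- list()
  for (w in weeks) {
    days <- dates[wk_all == w & ok]
    if (!length(days)) next
    lagged <- build_lags(weather, days)          # daily lags first
    wk_weather <- colMeans(lagged)               # then weekly mean
    g <- grid
    g$week <- w
    for (v in mains) {
      # a bare weather name denotes its same-day (lag-0) daily value
      wname <- if (v %in% names(wk_weather)) v else paste0(v, "_lag0")
      x <- if (wname %in% names(wk_weather)) wk_weather[[wname]] else g[[v]]
      if (is.null(x)) stop("missing covariate for term: ", v)
      g[[v]] <- std1(v, x)
    }
    for (ab in inter) {
      pa <- strsplit(ab, ":", fixed = TRUE)[[1]]
      g[[ab]] <- g[[pa[1]]] * g[[pa[2]]]
    }
    rows[[length(rows) + 1L]] <- g
  }
  do.call(rbind, rows)
}
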