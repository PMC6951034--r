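# Design-matrix construction: standardization with frozen constants, daily
# weather lags, correlated-pair screening and interaction columns.

#' Centre and scale a covariate
#'
#' Subtracts the mean and divides by the (sample) standard deviation, so a
#' value of zero represents the mean and units are standard deviations.
#' Stored constants allow the exact inverse transform and, crucially, allow
#' prediction-time covariates to be transformed with the *training*
#' constants.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @param center,scale optional frozen constants; when supplied they are used
#'   instead of the sample mean/sd (prediction-time use).
#' @return list with `x` (standardized vector), `center`, `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2)
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) stop("zero variance: cannot standardize")
  list(x = (x - center) / scale, center = center, scale = scale)
}

#' Invert a standardization
#' @param z standardized values.
#' @param center,scale the constants stored by [standardize()].
#' @export
destandardize <- function(z, center, scale) z * scale + center

#' Build daily weather lag columns for observation dates
#'
#' For each observation date t, the lag-k column holds the single daily value
#' at t - 7k days (k = 0, 1, 2 by default): the value on the day of the
#' observation, 7 days previously and 14 days previously — not a weekly mean.
#'
#' @param series data frame with a `date` column and one or more numeric
#'   weather columns.
#' @param obs_dates vector of observation `Date`s.
#' @param lags lag offsets in days; default `c(0, 7, 14)`.
#' @return data frame with one row per observation and columns
#'   `<var>_lag<k>` (lag index k = days/7), in natural units.
#' @export
build_lags <- function(series, obs_dates, lags = c(0, 7, 14)) {
  stopifnot("date" %in% names(series))
  obs_dates <- as.Date(obs_dates)
  sdate <- as.Date(series$date)
  vars <- setdiff(names(series), "date")
  out <- list()
  for (k in lags) {
    want <- obs_dates - k
    miss <- setdiff(as.character(want), as.character(sdate))
    if (length(miss))
      stop("weather series does not cover date ", miss[1],
           " (needed for lag ", k, ")")
    idx <- match(as.character(want), as.character(sdate))
    for (v in vars)
      out[[sprintf("%s_lag%d", v, k %/% 7)]] <- series[[v]][idx]
  }
  as.data.frame(out)
}

#' Flag correlated covariate pairs
#'
#' All unordered column pairs whose absolute Spearman rank correlation
#' (average ranks for ties) exceeds the threshold.
#'
#' @param design numeric matrix or data frame, >= 3 rows.
#' @param threshold default 0.5.
#' @return data frame with columns `a`, `b`, `rho`, possibly zero rows.
#' @export
flag_correlated_pairs <- function(design, threshold = 0.5) {
  X <- as.matrix(design)
  stopifnot(nrow(X) >= 3)
  R <- stats::cor(X, method = "spearman")
  out <- data.frame(a = character(), b = character(), rho = numeric())
  nm <- colnames(R)
  for (i in seq_len(ncol(R) - 1)) for (j in (i + 1):ncol(R)) {
    if (is.finite(R[i, j]) && abs(R[i, j]) > threshold)
      out <- rbind(out, data.frame(a = nm[i], b = nm[j], rho = R[i, j]))
  }
  out
}

#' Append an interaction column
#'
#' The interaction is the elementwise product of the *standardized* parent
#' columns and is deliberately not re-standardized, so its coefficient reads
#' as the modification of one parent's effect per SD of the other.
#'
#' @param design numeric matrix or data frame.
#' @param a,b parent column names.
#' @return `design` with an appended column named `"a:b"`.
#' @export
add_interaction <- function(design, a, b) {
  design <- as.data.frame(design, optional = TRUE)
  nm <- colnames(design)
  if (!all(c(a, b) %in% nm))
    stop("columns not found: ", paste(setdiff(c(a, b), nm), collapse = ", "))
  new <- paste(a, b, sep = ":")
  if (new %in% nm || paste(b, a, sep = ":") %in% nm)
    stop("duplicate interaction: ", new)
  out <- cbind(as.data.frame(design),
               stats::setNames(data.frame(design[[a]] * design[[b]]), new))
  out
}

#' Standardize a set of covariate columns with frozen constants
#'
#' Standardizes every column of `covariates` (or applies previously frozen
#' `scaling`), returning the design and a scaling table for later
#' prediction-time use.
#'
#' @param covariates data frame of numeric columns in natural units.
#' @param scaling optional scaling table from a previous call (columns
#'   `column`, `center`, `scale`).
#' @return list with `design` (data frame, standardized) and `scaling`.
#' @export
standardize_design <- function(covariates, scaling = NULL) {
  covariates <- as.data.frame(covariates)
  if (is.null(scaling)) {
    sc <- lapply(covariates, standardize)
    design <- as.data.frame(lapply(sc, `[[`, "x"))
    scaling <- data.frame(column = names(sc),
                          center = vapply(sc, `[[`, 0, "center"),
                          scale = vapply(sc, `[[`, 0, "scale"),
                          row.names = NULL)
  } else {
    stopifnot(all(names(covariates) %in% scaling$column))
    design <- covariates
    for (v in names(covariates)) {
      i <- match(v, scaling$column)
      design[[v]] <- (covariates[[v]] - scaling$center[i]) / scaling$scale[i]
    }
  }
  list(design = design, scaling = scaling)
}

#' Write / read a design matrix with its scaling sidecar
#'
#' The design goes to CSV; per-column centers, scales and lag tags go to a
#' JSON sidecar `<path>.json` so prediction-time covariates can be
#' transformed with the training constants.
#' @param design data frame; `scaling` the table from [standardize_design()].
#' @param path CSV path.
#' @export
write_design <- function(design, scaling, path) {
  utils::write.csv(design, path, row.names = FALSE)
  jsonlite::write_json(scaling, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  list(design = utils::read.csv(path, check.names = FALSE),
       scaling = jsonlite::fromJSON(paste0(path, ".json")))
}
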