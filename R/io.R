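# Table readers/writers, site filtering, configuration and the end-to-end
# pipeline driver.

#' Read a long-format trap observation table
#'
#' Expects CSV columns `site_id`, `easting_km`, `northing_km`, `date`
#' (ISO-8601), `species`, `count`. Counts must be non-negative integers.
#' Duplicate (site, date, species) rows are kept — multiple trap-nights are
#' allowed — with a warning.
#'
#' @param path CSV path.
#' @return validated data frame with `date` parsed as `Date`.
#' @export
read_trap_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "easting_km", "northing_km", "date", "species", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$count) | tab$count < 0 | tab$count != round(tab$count))
  if (length(bad)) stop("negative or non-integer count at row ", bad[1])
  d <- as.Date(tab$date, format = "%Y-%m-%d")
  if (anyNA(d)) stop("malformed date at row ", which(is.na(d))[1])
  tab$date <- d
  dup <- duplicated(tab[, c("site_id", "date", "species")])
  if (any(dup))
    warning(sum(dup), " duplicate (site, date, species) rows kept ",
            "(multiple trap-nights allowed)")
  tab
}

#' Drop sparsely observed trap sites
#'
#' Removes sites with fewer than `min_obs` rows (a site with exactly
#' `min_obs` is retained).
#'
#' @param table trap observation table.
#' @param min_obs retention threshold; default 30.
#' @return list with `data` (filtered table) and `report` (dropped site ids,
#'   retained site/observation totals).
#' @export
filter_sparse_sites <- function(table, min_obs = 30) {
  n_by_site <- table(table$site_id)
  drop <- names(n_by_site)[n_by_site < min_obs]
  out <- table[!table$site_id %in% drop, , drop = FALSE]
  if (nrow(out) == 0) stop("all sites dropped (min_obs = ", min_obs, ")")
  list(data = out,
       report = list(dropped_sites = drop,
                     n_sites_retained = length(unique(out$site_id)),
                     n_obs_retained = nrow(out)))
}

#' Write a prediction surface as GeoJSON points
#'
#' @param cells per-cell prediction data frame (see [predict_weekly()]).
#' @param path output path.
#' @export
write_geojson <- function(cells, path) {
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(cells$easting_km[i],
                                         cells$northing_km[i])),
         properties = as.list(cells[i, setdiff(names(cells),
                                               c("easting_km", "northing_km"))]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]; unknown keys are rejected.
#'
#' @param scenario `"aegypti"` or `"albopictus"` generator scenario.
#' @param n_sites,extent_km,mean_obs layout settings.
#' @param chains,iter MCMC settings for the final fit.
#' @param n_select_iter spike-and-slab chain length.
#' @param n_sims posterior-predictive simulations.
#' @param grid_n grid cells per side for prediction maps.
#' @param seed master seed; all stage seeds derive from it.
#' @param on_nonconvergence `"error"` (default) or `"warn"`, forwarded to
#'   [fit_count_model()] (demo-scale runs may accept marginal chains).
#' @param ... rejected (schema validation).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "aegypti", n_sites = 51,
                            extent_km = 11.3, mean_obs = 100,
                            chains = 2, iter = 2000, n_select_iter = 2000,
                            n_sims = 500, grid_n = 8, seed = 1L,
                            on_nonconvergence = "error", ...) {
  extra <- list(...)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(names(extra), collapse = ", "))
  stopifnot(scenario %in% c("aegypti", "albopictus"),
            n_sites >= 2, extent_km > 0, chains >= 2,
            on_nonconvergence %in% c("error", "warn"))
  structure(list(scenario = scenario, n_sites = n_sites,
                 extent_km = extent_km, mean_obs = mean_obs, chains = chains,
                 iter = iter, n_select_iter = n_select_iter, n_sims = n_sims,
                 grid_n = grid_n, seed = as.integer(seed),
                 on_nonconvergence = on_nonconvergence),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline: simulate, preprocess, select, fit, validate, predict
#'
#' Executes every stage on a synthetic scenario dataset, writing per-stage
#' CSV/JSON outputs and a provenance manifest (seeds, package version, file
#' hashes) under `out_dir`. Deterministic given the same config: rerunning
#' reproduces identical file hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of stage results; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ", appendLF = FALSE)
    t0 <- Sys.time()
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  cfg <- if (config$scenario == "aegypti") scenario_aegypti(config$seed)
         else scenario_albopictus(config$seed)
  sim <- stage("simulate", {
    layout <- generate_sites(config$n_sites, config$extent_km,
                             config$mean_obs, seed = config$seed + 1000L)
    s <- simulate_counts(layout, cfg)
    tab <- s$data
    tab$species <- config$scenario
    utils::write.csv(
      tab[, c("site_id", "easting_km", "northing_km", "date", "species", "count")],
      file.path(out_dir, "traps.csv"), row.names = FALSE)
    utils::write.csv(cbind(tab[, "site_id", drop = FALSE], s$design),
                     file.path(out_dir, "covariates.csv"), row.names = FALSE)
    s
  })

  prep <- stage("preprocess", {
    # generator covariates are already on the standardized scale; freeze
    # their constants from the fitting data all the same
    mains <- colnames(sim$design)[!grepl(":", colnames(sim$design), fixed = TRUE)]
    sd_out <- standardize_design(as.data.frame(sim$design)[mains])
    design <- sd_out$design
    for (ab in setdiff(colnames(sim$design), mains)) {
      pa <- strsplit(ab, ":", fixed = TRUE)[[1]]
      design <- add_interaction(design, pa[1], pa[2])
    }
    pairs <- flag_correlated_pairs(design[mains])
    write_design(design, sd_out$scaling, file.path(out_dir, "design.csv"))
    list(design = design, scaling = sd_out$scaling, pairs = pairs)
  })

  sel <- stage("select", {
    mains <- names(prep$design)[!grepl(":", names(prep$design), fixed = TRUE)]
    r <- spike_slab_select(sim$data$count, prep$design[mains],
                           n_iter = config$n_select_iter,
                           burn_in = config$n_select_iter %/% 4,
                           seed = config$seed + 2L)
    utils::write.csv(r$ranking, file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
    r
  })

  fit <- stage("fit", {
    f <- fit_count_model(
      sim$data$count, prep$design, sites = sim$data$site_id,
      coords = sim$layout, family = cfg$family, spatial = TRUE,
      chains = config$chains, iter = config$iter, seed = config$seed + 3L,
      on_nonconvergence = config$on_nonconvergence)
    utils::write.csv(coef_summary(f), file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    d <- dic(f); o <- overdispersion_stat(f)
    jsonlite::write_json(
      list(dic = d$dic, pd = d$pd,
           overdispersion = o,
           rhat = stats::setNames(as.list(f$diagnostics$rhat),
                                  f$diagnostics$param)),
      file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
    f
  })

  val <- stage("validate", {
    pp <- posterior_predictive(fit, n_sims = config$n_sims,
                               seed = config$seed + 4L)
    utils::write.csv(pp$bands, file.path(out_dir, "predictive_bands.csv"),
                     row.names = FALSE)
    sr <- scaled_residuals(fit, pp)
    utils::write.csv(sr$quantiles, file.path(out_dir, "residual_envelope.csv"),
                     row.names = FALSE)
    list(pp = pp, sr = sr)
  })

  pred <- stage("predict", {
    gseq <- seq(0, config$extent_km, length.out = config$grid_n)
    grid <- expand.grid(easting_km = gseq, northing_km = gseq)
    u <- interpolate_field(fit, grid, n_draws = 100,
                           seed = config$seed + 5L)
    utils::write.csv(u, file.path(out_dir, "spatial_effect.csv"),
                     row.names = FALSE)
    terms <- setdiff(colnames(fit$X), "(Intercept)")
    set.seed(config$seed + 6L)
    # weekly demo covariates at the training mean with a seasonal wiggle
    weeks <- 1:52
    gc_rows <- lapply(weeks, function(w) {
      g <- grid; g$week <- w
      for (v in terms) g[[v]] <- 0
      wig <- sinpi(2 * w / 52)
      if ("humidity" %in% terms) g$humidity <- wig
      if ("temperature_lag1" %in% terms) g$temperature_lag1 <- wig
      if ("humidity_lag2" %in% terms) g$humidity_lag2 <- wig
      for (ab in terms[grepl(":", terms, fixed = TRUE)]) {
        pa <- strsplit(ab, ":", fixed = TRUE)[[1]]
        g[[ab]] <- g[[pa[1]]] * g[[pa[2]]]
      }
      g
    })
    ps <- predict_weekly(fit, do.call(rbind, gc_rows), n_draws = 100,
                         seed = config$seed + 7L)
    utils::write.csv(ps$weekly, file.path(out_dir, "weekly_predictions.csv"),
                     row.names = FALSE)
    peak <- ps$weekly$week[which.max(ps$weekly$sum_mean)]
    write_geojson(ps$cells[ps$cells$week == peak, ],
                  file.path(out_dir, "peak_week_map.geojson"))
    ps
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("aedesmapr")),
    seed = config$seed,
    scenario = config$scenario,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, prep = prep, selection = sel, fit = fit,
                 validation = val, prediction = pred, manifest = manifest))
}
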