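#!/usr/bin/env Rscript
# Stage 4: family comparison by DIC (Poisson, ZIP, NB, NB + spatial) and the
# final negative-binomial spatial fit per species, with coefficient and
# hyperparameter tables and the Pearson overdispersion statistic.

library(aedesmapr)

out <- "results/analysis"
seed <- 2017L

for (sc in c("aegypti", "albopictus")) {
  traps <- read_trap_table(file.path(out, paste0("traps_", sc, ".csv")))
  design <- read_design(file.path(out, paste0("design_", sc, ".csv")))$design
  sites <- read.csv(file.path(out, paste0("sites_", sc, ".csv")))

  cm <- compare_models(
    list(list(family = "poisson", spatial = FALSE, label = "poisson"),
         list(family = "zip", spatial = FALSE, label = "zip"),
         list(family = "negbin", spatial = FALSE, label = "negbin"),
         list(family = "negbin", spatial = TRUE, label = "negbin+spatial")),
    y = traps$count, X = design, sites = traps$site_id, coords = sites,
    chains = 2, iter = 2000, seed = seed + 13L,
    on_nonconvergence = "warn")
  write.csv(cm$table, file.path(out, paste0("dic_", sc, ".csv")),
            row.names = FALSE)
  cat(sprintf("\n%s model comparison (lower DIC is better):\n", sc))
  print(cm$table[, c("label", "dic", "pd", "best")], row.names = FALSE)

  fit <- cm$fits[["negbin+spatial"]]
  saveRDS(fit, file.path(out, paste0("fit_", sc, ".rds")))
  write.csv(coef_summary(fit),
            file.path(out, paste0("coefficients_", sc, ".csv")),
            row.names = FALSE)
  write.csv(hyper_summary(fit),
            file.path(out, paste0("hyperparameters_", sc, ".csv")),
            row.names = FALSE)
  o <- overdispersion_stat(fit)
  cat(sprintf("overdispersion %.2f [%.2f, %.2f]; ", o$estimate, o$lower,
              o$upper))
  hs <- hyper_summary(fit)
  cat(sprintf("range %.2f km [%.2f, %.2f]\n",
              hs$median[hs$param == "range_km"],
              hs$lower[hs$param == "range_km"],
              hs$upper[hs$param == "range_km"]))
  print(fit)
}
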