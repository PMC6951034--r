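#!/usr/bin/env Rscript
# Stage 1: generate the synthetic surveillance datasets.
#
# Two scenarios mirror the two Aedes species: an abundant species with ~18%
# zero trap-nights and a rare species with >75% zeros, both over 51 sites in
# an ~11.3 km square (mean inter-site distance ~5.9 km), with a shared daily
# weather year and a sub-kilometre Matern spatial field.

library(aedesmapr)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2017L

weather <- generate_weather("2017-01-01", "2017-12-31", seed = seed)
write.csv(weather, file.path(out, "weather.csv"), row.names = FALSE)
cat(sprintf("weather: %d days, Spearman rho(temp, humidity) = %.2f\n",
            nrow(weather),
            cor(weather$temperature, weather$humidity, method = "spearman")))

for (sc in c("aegypti", "albopictus")) {
  cfg <- if (sc == "aegypti") scenario_aegypti(seed) else scenario_albopictus(seed)
  sim <- simulate_scenario(cfg, n_sites = 51, mean_obs = 100)
  tab <- sim$data
  tab$species <- sc
  write.csv(tab[, c("site_id", "easting_km", "northing_km", "date",
                    "species", "count")],
            file.path(out, paste0("traps_", sc, ".csv")), row.names = FALSE)
  write.csv(cbind(tab[, c("site_id", "date")], as.data.frame(sim$design)),
            file.path(out, paste0("covariates_", sc, ".csv")),
            row.names = FALSE)
  write.csv(sim$layout, file.path(out, paste0("sites_", sc, ".csv")),
            row.names = FALSE)
  cat(sprintf("%-10s: %d obs at %d sites, %.1f%% zeros, max count %d\n",
              sc, nrow(tab), nrow(sim$layout), 100 * mean(tab$count == 0),
              max(tab$count)))
}
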