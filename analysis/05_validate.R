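#!/usr/bin/env Rscript
# Stage 5: posterior-predictive simulation study (1,000 simulated datasets
# from 1,000 posterior draws) with count-histogram bands, and the scaled
# residual envelope.

library(aedesmapr)

out <- "results/analysis"
seed <- 2017L

for (sc in c("aegypti", "albopictus")) {
  fit <- readRDS(file.path(out, paste0("fit_", sc, ".rds")))
  pp <- posterior_predictive(fit, n_sims = 1000, seed = seed + 17L)
  write.csv(pp$bands, file.path(out, paste0("predictive_bands_", sc, ".csv")),
            row.names = FALSE)
  sr <- scaled_residuals(fit, pp)
  write.csv(sr$quantiles,
            file.path(out, paste0("residual_envelope_", sc, ".csv")),
            row.names = FALSE)
  zero_row <- pp$bands[pp$bands$count == 0, ]
  cat(sprintf(
    "%s: %.1f%% of count bins inside the 95%% band; observed zeros %d vs band [%g, %g]; %d/%d residual quantiles flagged\n",
    sc, 100 * pp$coverage, zero_row$observed, zero_row$lower, zero_row$upper,
    sr$n_flagged, nrow(sr$quantiles)))

  pdf(file.path(out, paste0("fig_predictive_", sc, ".pdf")), 7, 5)
  b <- pp$bands[pp$bands$count <= 30, ]
  plot(b$count, b$observed, type = "h", lwd = 2,
       xlab = "mosquitoes per trap-night", ylab = "frequency",
       main = sprintf("Posterior-predictive check (%s scenario)", sc))
  polygon(c(b$count, rev(b$count)), c(b$lower, rev(b$upper)),
          col = grDevices::adjustcolor("steelblue", 0.4), border = NA)
  lines(b$count, b$observed, type = "h", lwd = 2)
  dev.off()
}
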