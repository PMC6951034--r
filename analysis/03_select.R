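#!/usr/bin/env Rscript
# Stage 3: spike-and-slab variable selection. Candidates are ranked by
# posterior inclusion probability; per weather variable only the
# largest-effect lag is considered, and the final six predictors are the
# largest absolute scaled effects among the top inclusion probabilities.

library(aedesmapr)

out <- "results/analysis"
seed <- 2017L

for (sc in c("aegypti", "albopictus")) {
  traps <- read_trap_table(file.path(out, paste0("traps_", sc, ".csv")))
  design <- read_design(file.path(out, paste0("design_", sc, ".csv")))$design
  mains <- names(design)[!grepl(":", names(design), fixed = TRUE)]
  sel <- spike_slab_select(traps$count, design[mains],
                           n_iter = 3000, burn_in = 1000, seed = seed + 7L)
  groups <- list()
  for (v in c("temperature", "humidity", "shortwave", "precipitation")) {
    g <- grep(paste0("^", v, "(_lag[0-2])?$"), mains, value = TRUE)
    if (length(g) > 1) groups[[v]] <- g
  }
  chosen <- choose_top_six(sel, weather_groups = groups)
  write.csv(sel$ranking, file.path(out, paste0("selection_", sc, ".csv")),
            row.names = FALSE)
  writeLines(chosen, file.path(out, paste0("chosen_", sc, ".txt")))
  cat(sprintf("%s top of ranking:\n", sc))
  print(head(sel$ranking, 8), row.names = FALSE)
  cat("  chosen:", paste(chosen, collapse = ", "), "\n\n")
}
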