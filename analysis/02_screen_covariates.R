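#!/usr/bin/env Rscript
# Stage 2: validate the survey tables, apply the exclusion rules, and
# screen covariates for collinearity before any model sees them.
#
# Human metrics and reef area are log-transformed (log(x+1) for humans,
# which include exact zeros) and all covariates standardized. Pairs with
# |r| > 0.7 cannot enter a model together; reef area vs minimum SST is
# the structural confounding that splits the candidates into model sets
# A (temperature) and B (reef area).

library(sharkbaseline)
library(jsonlite)

tows <- read_tow_table("results/tows.csv")
islands <- read_island_table("results/islands.csv")

flt <- filter_tows(tows)
cat("Exclusions:", toJSON(flt$excluded, auto_unbox = TRUE), "\n")
write_json(flt$excluded, "results/exclusions.json", auto_unbox = TRUE)
tows <- flt$kept

islands$mean_complexity <- as.numeric(
  island_mean_complexity(tows)[islands$island_id])
design <- transform_covariates(islands)

scr <- correlation_screen(design, threshold = 0.7)
cat("Flagged covariate pairs (|r| > 0.7):\n")
print(scr$flagged_pairs)
cat(sprintf("r(log reef area, min SST) = %.2f\n",
            scr$pairwise_r["reef_area_km2", "min_sst"]))

v <- vif(design, c("humans_200km", "productivity", "min_sst",
                   "mean_complexity"))
cat("VIFs of the temperature-set covariates:\n")
print(round(v, 2))

write_json(list(pairwise_r = scr$pairwise_r,
                flagged = scr$flagged_pairs, vif = as.list(v)),
           "results/collinearity.json", digits = NA)

sets <- build_model_sets()
cat("Candidate subsets: set A", length(sets$A), "models, set B",
    length(sets$B), "models; SST and reef area never co-occur.\n")

saveRDS(list(tows = tows, islands = islands, design = design,
             sets = sets), "scratch/prepared.rds")
cat("Wrote collinearity.json, exclusions.json, prepared.rds\n")
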