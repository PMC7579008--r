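#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study region.
#
# Generates the study-like landscape (250 x 250 cells at 30 arc-seconds,
# 18 continuous + 2 categorical predictors), the population and urban
# rasters, the region tiling, and 150,000 clustered arsenic sample points
# whose exceedance mechanism is a known logistic model calibrated to a 42%
# aggregated exceedance rate. Everything is written as plain text under
# results/landscape/.

suppressPackageStartupMessages(library(ashazard))

seed <- 1L
out <- "results/landscape"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scen <- paper_like_scenario(seed = seed)

write.csv(scen$points, file.path(out, "points.csv"), row.names = FALSE)
for (nm in names(scen$landscape$predictors))
  write_ascii_grid(scen$landscape$predictors[[nm]],
                   file.path(out, paste0(nm, ".asc")))
write_ascii_grid(scen$landscape$population, file.path(out, "population.asc"))
write_ascii_grid(scen$landscape$urban, file.path(out, "urban.asc"))
write_ascii_grid(scen$landscape$regions, file.path(out, "regions.asc"))
write.csv(scen$landscape$region_names, file.path(out, "region_names.csv"),
          row.names = FALSE)

# categorical layers need their level sets to survive the text round trip
levels_map <- Filter(Negate(is.null),
                     lapply(scen$landscape$predictors, `[[`, "levels"))
jsonlite::write_json(levels_map, file.path(out, "layer_levels.json"))

truth <- list(intercept = scen$model$intercept,
              linear = as.list(scen$model$linear),
              peaked = lapply(scen$model$peaked, as.list),
              seed = seed)
jsonlite::write_json(truth, file.path(out, "true_model.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d points on a %d x %d grid; true intercept %.3f\n",
            nrow(scen$points), nrow(scen$landscape$population$values),
            ncol(scen$landscape$population$values), scen$model$intercept))
cat(sprintf("point-level exceedance rate: %.3f\n", mean(scen$points$exceed)))
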