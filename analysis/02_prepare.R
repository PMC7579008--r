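#!/usr/bin/env Rscript
# Stage 2 — build the modeling table.
#
# Reads the raw sample points and predictor rasters written by
# 01_simulate.R, averages points to the 1-km prediction grid, recodes the
# mean concentration at the 10 ug/L guideline, joins every predictor, and
# writes results/modeling_table.csv.

suppressPackageStartupMessages(library(ashazard))

land_dir <- "results/landscape"
points <- read.csv(file.path(land_dir, "points.csv"))

levels_map <- jsonlite::read_json(file.path(land_dir, "layer_levels.json"),
                                  simplifyVector = TRUE)
layer_files <- list.files(land_dir, pattern = "^(cont|cat)_.*\\.asc$",
                          full.names = TRUE)
layers <- lapply(layer_files, read_ascii_grid)
names(layers) <- sub("\\.asc$", "", basename(layer_files))
for (nm in names(levels_map)) layers[[nm]]$levels <- levels_map[[nm]]
predictors <- raster_stack(layers)

table <- build_modeling_table(points[c("lon", "lat", "as_ugL")], predictors,
                              threshold = 10)

write.csv(table, "results/modeling_table.csv", row.names = FALSE)
cat(sprintf("aggregated %d raw points to %d cells (%d dropped on nodata)\n",
            attr(table, "n_input"), attr(table, "n_aggregated"),
            attr(table, "n_dropped")))
cat(sprintf("exceedance fraction after aggregation: %.3f\n",
            mean(table$label)))
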