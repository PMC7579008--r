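#!/usr/bin/env Rscript
# Stage 4 — hazard maps and population at risk.
#
# Thresholds the probability map at the two cutoffs found in stage 3,
# weights the population in high-hazard cells by the modeled probability
# and the rural/urban untreated-groundwater use rates (0.637 / 0.238), and
# writes the per-region exposure report.

suppressPackageStartupMessages(library(ashazard))

prob_map <- read_ascii_grid("results/probability_map.asc")
land_dir <- "results/landscape"
population <- read_ascii_grid(file.path(land_dir, "population.asc"))
urban <- read_ascii_grid(file.path(land_dir, "urban.asc"))
regions <- read_ascii_grid(file.path(land_dir, "regions.asc"))
region_names <- read.csv(file.path(land_dir, "region_names.csv"))

cutoff_of <- function(crit) {
  cv <- read.csv(sprintf("results/cutoff_curves_%s.csv", crit))
  a <- if (crit == "sens_spec") abs(cv$sensitivity - cv$specificity)
  else abs(cv$ppv - cv$npv)
  a[c(1, nrow(cv))] <- NA
  cv$cutoff[which.min(a)]
}
cutoffs <- c(cutoff_of("sens_spec"), cutoff_of("ppv_npv"))
cat(sprintf("cutoffs: %.3f (sens/spec), %.3f (ppv/npv)\n",
            cutoffs[1], cutoffs[2]))

cfg <- exposure_config(cutoffs = cutoffs)
for (ct in cutoffs)
  write_ascii_grid(hazard_map(prob_map, ct),
                   sprintf("results/hazard_map_%g.asc", ct))

report <- regional_summary(prob_map, population, urban, regions,
                           region_names, cfg)
write.csv(as.data.frame(report), "results/exposure_report.csv",
          row.names = FALSE)

tot <- report[report$region == "Total", ]
cat(sprintf("land area at risk: %.1f%% - %.1f%%\n",
            tot$pct_area_low, tot$pct_area_high))
cat(sprintf("population at risk: %.0f - %.0f people\n",
            tot$pop_low, tot$pop_high))
print(as.data.frame(report[c("region", "pct_area_low", "pct_area_high",
                             "pop_low", "pop_high")]), row.names = FALSE)
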