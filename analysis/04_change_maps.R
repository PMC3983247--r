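#!/usr/bin/env Rscript

# Stage 4: where the estimated distribution changed.
#
# Compares the baseline suitability raster with the adjusted model that
# produced the largest suitable + highly suitable area among the 54 design
# runs: per-cell category transitions, the 4 x 4 transition-area table,
# and the shift in occurrence-record validation counts.

suppressMessages(library(ecoclimex))
dir.create("results", showWarnings = FALSE)

world <- read_climate_csv("results/climate_world.csv")
baseline <- run_model(world, species_parameters())

runs <- read.csv("results/taguchi_runs_world.csv")
best <- runs$run[which.max(runs$response)]
design <- build_design()
adjusted <- run_model(world, design$parameters[[best]])
write_ei_csv(adjusted, "results/adjusted_ei.csv")
base_areas <- category_areas(baseline)
cat(sprintf("largest-response run: %d (suitable+high %.0f km^2 vs baseline %.0f km^2)\n",
            best, max(runs$response),
            base_areas$suitable + base_areas$highly_suitable))

cm <- change_map(baseline, adjusted)
write.csv(as.data.frame(as.table(cm$areas)), "results/change_map_areas.csv",
          row.names = FALSE)
changed <- sum(cm$areas) - sum(diag(cm$areas))
cat(sprintf("area changing category: %.0f km^2 (%.1f%% of the grid)\n",
            changed, 100 * changed / sum(cm$areas)))
up <- sum(cm$areas[upper.tri(cm$areas)])
down <- sum(cm$areas[lower.tri(cm$areas)])
cat(sprintf("  upgraded %.0f km^2, downgraded %.0f km^2\n", up, down))

occ <- filter_occurrences(read_occurrences("results/occurrences.csv"))$retained
cb <- occurrence_category_counts(occ, baseline)
ca <- occurrence_category_counts(occ, adjusted)
shift <- rbind(baseline = unlist(cb[1, 1:4]), adjusted = unlist(ca[1, 1:4]))
write.csv(shift, "results/validation_count_shift.csv")
cat("occurrence records per category (baseline vs adjusted):\n")
print(shift)
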