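#!/usr/bin/env Rscript

# Stage 2: the baseline suitability model.
#
# Runs the ecoclimatic model with the fitted date-palm parameters on the
# synthetic world from stage 1, writes the EI raster and its category
# areas, and validates the curated occurrence records against the raster.

suppressMessages(library(ecoclimex))
dir.create("results", showWarnings = FALSE)

world <- read_climate_csv("results/climate_world.csv")
params <- read_species_parameters(
  system.file("extdata", "species_phoenix_dactylifera.txt",
              package = "ecoclimex"))
baseline <- run_model(world, params)
write_ei_csv(baseline, "results/baseline_ei.csv")

areas <- category_areas(baseline)
write.csv(areas, "results/baseline_areas.csv", row.names = FALSE)
cat("baseline Ecoclimatic Index on the synthetic world:\n")
cat(sprintf("  EI range %.1f-%.1f; mean %.1f\n",
            min(baseline$ei, na.rm = TRUE), max(baseline$ei, na.rm = TRUE),
            mean(baseline$ei, na.rm = TRUE)))
cat(sprintf("  areas (km^2): unsuitable %.0f | marginal %.0f | suitable %.0f | highly suitable %.0f\n",
            areas$unsuitable, areas$marginal, areas$suitable,
            areas$highly_suitable))
cat(sprintf("  suitable + highly suitable: %.0f km^2 (%.1f%% of %.0f)\n",
            areas$suitable + areas$highly_suitable,
            100 * (areas$suitable + areas$highly_suitable) / areas$total,
            areas$total))

occ <- read_occurrences("results/occurrences.csv")
filt <- filter_occurrences(occ)
write_occurrences(filt$retained, "results/occurrences_retained.csv")
write.csv(filt$removed, "results/occurrences_removed.csv", row.names = FALSE)
cat(sprintf("occurrence curation: %d -> %d records (%d without coordinates removed)\n",
            nrow(occ), nrow(filt$retained), nrow(filt$removed)))

counts <- occurrence_category_counts(filt$retained, baseline)
write.csv(counts, "results/baseline_validation_counts.csv", row.names = FALSE)
cat(sprintf("records per category: unsuitable %d | marginal %d | suitable %d | highly suitable %d (out of grid %d)\n",
            counts$unsuitable, counts$marginal, counts$suitable,
            counts$highly_suitable, counts$out_of_grid))
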