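#!/usr/bin/env Rscript

# Stage 1: build the study's driving data.
#
# Generates the seeded synthetic world (monthly climate normals at 0.5
# degrees over a monsoonal humid-to-arid gradient, 6-24 N x 44-64 E), the
# two engineered single-axis climates used by the sensitivity recovery
# study, and places the packaged 145-record occurrence fixture alongside
# them.  Everything downstream reads from results/.

suppressMessages(library(ecoclimex))
dir.create("results", showWarnings = FALSE)

seed <- 1L
spec <- grid_spec(6, 24, 44, 64, 0.5)
scenario <- climate_scenario(seed = seed)
world <- generate_climate(spec, scenario)
write_climate_csv(world, "results/climate_world.csv")
cat(sprintf("synthetic world: %d x %d cells at %.1f deg, seed %d\n",
            length(spec$lats), length(spec$lons), spec$resolution, seed))
annual_p <- apply(world$precip, c(1, 2), sum)
cat(sprintf("  annual precipitation spans %.0f-%.0f mm along the gradient\n",
            min(annual_p), max(annual_p)))

rec_spec <- grid_spec(5, 25, 40, 60, 1)
write_climate_csv(climate_temperature_limited(rec_spec),
                  "results/climate_temperature_limited.csv")
write_climate_csv(climate_moisture_limited(rec_spec),
                  "results/climate_moisture_limited.csv")
cat("engineered single-axis climates written (20 x 20 cells each)\n")

occ <- read_occurrences(system.file("extdata", "occurrences_synthetic.csv",
                                    package = "ecoclimex"))
write_occurrences(occ, "results/occurrences.csv")
cat(sprintf("occurrence fixture: %d records, %d without coordinates\n",
            nrow(occ), sum(is.na(occ$lat) | is.na(occ$lon))))
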