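# Regenerates the plain-text fixtures under inst/extdata/.
# Run from the package root: Rscript data-raw/make_fixtures.R
devtools::load_all(".", quiet = TRUE)

# canonical L54(2^1 x 3^25) orthogonal array
a <- oa54_mixed()
validate_orthogonal_array(a)
write.csv(a, "inst/extdata/oa54.csv", row.names = FALSE)

# baseline date-palm parameter file
write_species_parameters(species_parameters(),
                         "inst/extdata/species_phoenix_dactylifera.txt")

# factor-level table: level 2 is the baseline value throughout
ft <- data.frame(
  factor = c("SM0", "SM1", "SM2", "SM3", "DV0", "DV1", "DV2", "DV3",
             "TTCS", "THCS", "TTHS", "THHS", "SMWS", "HWS"),
  level1 = c(0.005, 0.011, 0.5, 0.6, 10, 15, 30, 40, 2, -0.05, 40, 0.7, 0.6, 0.018),
  level2 = c(0.007, 0.013, 0.81, 0.9, 14, 20, 39, 46, 4, -0.01, 46, 0.9, 0.9, 0.022),
  level3 = c(0.01, 0.017, 1, 1, 18, 26, 45, 50, 5, 0, 50, 1, 1, 0.029))
write.csv(ft, "inst/extdata/factor_levels.csv", row.names = FALSE)

# synthetic occurrence fixture: 145 records, 19 without coordinates
spec <- grid_spec(6, 24, 44, 64, 0.5)
occ <- generate_occurrences(145, 19, spec, seed = 20140410 %% 1000)
write_occurrences(occ, "inst/extdata/occurrences_synthetic.csv")
cat("fixtures written\n")
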