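test_that("the packaged array equals the constructive array and validates", {
  a <- load_orthogonal_array()
  expect_identical(unname(a), unname(oa54_mixed()))
  expect_identical(dim(a), c(54L, 26L))
})

test_that("corrupted arrays are rejected with a diagnostic", {
  a <- oa54_mixed()
  a[1, 2] <- a[1, 2] %% 3 + 1L
  expect_error(validate_orthogonal_array(a), "balance")
  expect_error(validate_orthogonal_array(oa54_mixed()[1:53, ]), "54")
})

test_that("the packaged factor table holds three levels around the baseline", {
  ft <- read_factor_table()
  expect_equal(nrow(ft), 14)
  expect_setequal(ft$factor, parameter_codes())
  base <- species_parameters()
  for (f in seq_len(nrow(ft)))
    expect_equal(ft$level2[f], base[[ft$factor[f]]])
  expect_equal(ft$level1[ft$factor == "DV2"], 30)
  expect_equal(ft$level3[ft$factor == "SM3"], 1)
})

test_that("the design materializes 54 repaired parameter sets", {
  des <- build_design()
  expect_equal(length(des$parameters), 54)
  expect_equal(dim(des$levels), c(54L, 14L))
  for (p in des$parameters) expect_s3_class(p, "species_parameters")
  # ordering repairs happened and were logged (e.g. DV2 = 45 with DV3 = 40)
  expect_gt(nrow(des$repairs), 0)
  dv3_fix <- subset(des$repairs, knot == "DV3")
  expect_true(all(dv3_fix$to == 45.1))
  bad_runs <- which(des$values[, "DV2"] == 45 & des$values[, "DV3"] == 40)
  expect_setequal(dv3_fix$run, bad_runs)
  for (r in bad_runs) expect_equal(des$parameters[[r]]$DV3, 45.1)
})

test_that("a run with every factor at level 2 reproduces the baseline", {
  toy <- matrix(2L, 1, 26); toy[1, 1] <- 1L
  des <- build_design(toy, read_factor_table())
  expect_equal(unclass(des$parameters[[1]]), unclass(species_parameters()),
               tolerance = 1e-12)
  expect_equal(nrow(des$repairs), 0)
})

test_that("a single-factor toy design varies only that factor", {
  toy <- matrix(2L, 3, 26); toy[, 1] <- 1L
  toy[, 2] <- 1:3
  ft <- read_factor_table()
  des <- build_design(toy, ft[ft$factor == "DV0", ], columns = 1L)
  dv0 <- vapply(des$parameters, `[[`, numeric(1), "DV0")
  expect_equal(dv0, c(10, 14, 18))
  others <- setdiff(parameter_codes(), "DV0")
  for (nm in others)
    expect_equal(length(unique(vapply(des$parameters, `[[`, numeric(1), nm))), 1)
})

test_that("larger-the-better SN matches its closed forms and oracle", {
  expect_equal(sn_larger_better(1), 0)
  expect_equal(sn_larger_better(c(10, 10)), 20)
  expect_equal(sn_larger_better(c(1, 2, 4)), -10 * log10(0.4375),
               tolerance = 1e-12)
  expect_error(sn_larger_better(c(1, 0)), "positive")
  expect_error(sn_larger_better(-3), "positive")
  set.seed(12)
  for (i in 1:200) {
    y <- runif(sample(1:6, 1), 0.01, 1e6)
    expect_equal(sn_larger_better(y), -10 * log10(mean(1 / y^2)),
                 tolerance = 1e-12)
  }
})

fake_results <- function(sn) {
  data.frame(run = seq_along(sn), sn = sn, floored = FALSE)
}

test_that("identical responses give all-zero deltas", {
  des <- build_design()
  rep0 <- main_effects(des, fake_results(rep(3.7, 54)))
  expect_equal(rep0$delta, rep(0, 14))
  expect_equal(sort(rep0$rank), 1:14)
})

test_that("a response equal to one factor's level index isolates that factor", {
  des <- build_design()
  for (j in c(1, 7, 14)) {
    rep_j <- main_effects(des, fake_results(as.numeric(des$levels[, j])))
    expect_equal(rep_j$delta[j], 2)          # level means are exactly 1,2,3
    expect_equal(rep_j$delta[-j], rep(0, 13))  # forced by column balance
    expect_equal(rep_j$rank[j], 1)
    expect_equal(rep_j$opt_level[j], 3)
    series <- sensitivity_plot_data(rep_j)
    expect_equal(series$sn_mean[series$factor == rep_j$factor[j]],
                 c(1, 2, 3))
  }
})

test_that("level means conserve the total SN and shift equivariantly", {
  des <- build_design()
  set.seed(8)
  sn <- rnorm(54, 20, 5)
  rep1 <- main_effects(des, fake_results(sn))
  means <- as.matrix(rep1[, c("sn_level1", "sn_level2", "sn_level3")])
  expect_equal(unname(rowSums(means * 18)), rep(sum(sn), 14),
               tolerance = 1e-9)
  rep2 <- main_effects(des, fake_results(sn + 4.2))
  means2 <- as.matrix(rep2[, c("sn_level1", "sn_level2", "sn_level3")])
  expect_equal(means2, means + 4.2, tolerance = 1e-9)
  expect_equal(rep2$delta, rep1$delta, tolerance = 1e-9)
  expect_equal(rep2$rank, rep1$rank)
})

test_that("a degenerate factor (three identical levels) has zero delta", {
  # under an additive response the level means of a degenerate factor
  # coincide exactly by column balance
  des <- build_design()
  set.seed(2)
  effects <- matrix(rnorm(42), 14, 3)
  effects[14, ] <- 0                      # degenerate factor: no effect
  sn <- vapply(1:54, function(r)
    sum(effects[cbind(1:14, des$levels[r, ])]), numeric(1))
  rep1 <- main_effects(des, fake_results(sn))
  expect_lt(rep1$delta[14], 1e-12)
  # and through the real pipeline: identical levels leave every run's
  # parameters unchanged, so the factor cannot move the response
  ft <- read_factor_table()
  ft[ft$factor == "HWS", c("level1", "level3")] <- ft[ft$factor == "HWS", "level2"]
  des2 <- build_design(factors = ft)
  spec <- grid_spec(10, 20, 40, 50, 2)
  res <- execute_design(des2, climate_temperature_limited(spec))
  rep2 <- main_effects(des2, res)
  expect_lt(rep2$delta[rep2$factor == "HWS"], 1e-9)
})

test_that("executing a design is pure: permuted runs give the same responses", {
  spec <- grid_spec(10, 20, 40, 50, 2)
  norm <- climate_temperature_limited(spec)
  des <- build_design()
  keep <- c(3, 17, 29, 44, 51)
  small <- des
  small$parameters <- des$parameters[keep]
  small$levels <- des$levels[keep, ]
  res_a <- execute_design(small, norm)
  perm <- rev(seq_along(keep))
  small$parameters <- small$parameters[perm]
  res_b <- execute_design(small, norm)
  expect_equal(sort(res_a$response), sort(res_b$response))
  expect_equal(res_a$response[perm], res_b$response)
})

test_that("a baseline-only design reproduces the baseline model's area", {
  spec <- grid_spec(10, 20, 40, 50, 2)
  norm <- climate_temperature_limited(spec)
  toy <- matrix(2L, 1, 26); toy[1, 1] <- 1L
  des <- build_design(toy, read_factor_table())
  res <- execute_design(des, norm)
  areas <- category_areas(run_model(norm, species_parameters()))
  expect_equal(res$response, areas$suitable + areas$highly_suitable)
})

test_that("plot data has one ordered three-point series per factor", {
  des <- build_design()
  rep1 <- main_effects(des, fake_results(rnorm(54)))
  series <- sensitivity_plot_data(rep1)
  expect_equal(nrow(series), 42)
  expect_equal(unname(table(series$factor)), rep(3L, 14),
               ignore_attr = TRUE)
  expect_equal(series$level, rep(1:3, 14))
})
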