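# direct evaluation of the spherical band formula, independent of the
# package implementation
band_area <- function(lat, res) {
  6371^2 * (res * pi / 180) *
    (sin((lat + res / 2) * pi / 180) - sin((lat - res / 2) * pi / 180))
}

test_that("cell areas follow the spherical band formula", {
  expect_equal(cell_area_km2(0, 0.5), band_area(0, 0.5), tolerance = 1e-12)
  expect_equal(cell_area_km2(0, 0.5), 3091.1, tolerance = 1e-4)
  expect_equal(cell_area_km2(60, 0.5), band_area(60, 0.5), tolerance = 1e-12)
  # cos(60 deg) scaling of the equator value, to first order in resolution
  expect_equal(cell_area_km2(60, 0.5) / cell_area_km2(0, 0.5), 0.5,
               tolerance = 1e-4)
  lats <- seq(0, 89, by = 0.5)
  expect_true(all(diff(cell_area_km2(lats, 0.5)) < 0))
  expect_error(cell_area_km2(89.9, 0.5), "pole")
  expect_error(cell_area_km2(0, -1), "resolution")
})

# small raster builder with prescribed categories (EI chosen accordingly)
toy_raster <- function(categories, spec) {
  ei_for <- c(0, 5, 15, 35)
  cat_m <- matrix(categories, length(spec$lats), length(spec$lons))
  structure(list(grid = spec, ei = matrix(ei_for[cat_m], nrow(cat_m)),
                 category = cat_m), class = "ei_raster")
}

test_that("category areas partition the grid total", {
  spec <- grid_spec(10, 12, 20, 22, 1)
  all0 <- toy_raster(rep(1L, 4), spec)
  a <- category_areas(all0)
  expect_equal(a$unsuitable, a$total)
  expect_equal(a$marginal + a$suitable + a$highly_suitable, 0)

  one_each <- toy_raster(1:4, spec)   # column-major: one cell per category
  b <- category_areas(one_each)
  expect_equal(b$unsuitable, cell_area_km2(10.5, 1))
  expect_equal(b$marginal, cell_area_km2(11.5, 1))
  expect_equal(b$suitable, cell_area_km2(10.5, 1))
  expect_equal(b$highly_suitable, cell_area_km2(11.5, 1))

  set.seed(14)
  for (i in 1:20) {
    r <- toy_raster(sample(1:4, 4, replace = TRUE), spec)
    a <- category_areas(r)
    expect_equal(a$unsuitable + a$marginal + a$suitable + a$highly_suitable,
                 a$total, tolerance = 1e-9)
  }
})

test_that("change maps tabulate transitions with conserved marginals", {
  spec <- grid_spec(0, 3, 0, 3, 1)
  base <- toy_raster(rep(1L, 9), spec)
  same <- change_map(base, base)
  expect_equal(sum(diag(same$areas)), sum(same$areas))

  adj <- toy_raster(rep(3L, 9), spec)
  cm <- change_map(base, adj)
  expect_equal(cm$counts["unsuitable", "suitable"], 9)
  expect_equal(sum(cm$areas), cm$areas["unsuitable", "suitable"])
  expect_equal(cm$areas["unsuitable", "suitable"],
               category_areas(base)$total)

  set.seed(6)
  b2 <- toy_raster(sample(1:4, 9, TRUE), spec)
  a2 <- toy_raster(sample(1:4, 9, TRUE), spec)
  cm2 <- change_map(b2, a2)
  ab <- category_areas(b2); aa <- category_areas(a2)
  expect_equal(unname(rowSums(cm2$areas)),
               unname(unlist(ab[1, 1:4])), tolerance = 1e-9)
  expect_equal(unname(colSums(cm2$areas)),
               unname(unlist(aa[1, 1:4])), tolerance = 1e-9)

  other <- toy_raster(rep(1L, 4), grid_spec(0, 2, 0, 2, 1))
  expect_error(change_map(base, other), "grid")
})

test_that("the packaged occurrence fixture curates 145 records to 126", {
  occ <- read_occurrences(system.file("extdata", "occurrences_synthetic.csv",
                                      package = "ecoclimex"))
  expect_equal(nrow(occ), 145)
  f <- filter_occurrences(occ)
  expect_equal(nrow(f$retained), 126)
  expect_equal(nrow(f$removed), 19)
  expect_true(all(f$removed$reason == "missing coordinates"))
  expect_false(anyNA(f$retained$lat))
})

test_that("occurrence filtering preserves order and handles edge cases", {
  empty <- data.frame(id = character(), lat = numeric(), lon = numeric())
  expect_equal(nrow(filter_occurrences(empty)$retained), 0)
  complete <- data.frame(id = c("a", "b"), lat = c(1, 2), lon = c(3, 4))
  expect_identical(filter_occurrences(complete)$retained, complete)
  mixed <- data.frame(id = letters[1:4], lat = c(1, NA, 3, 4),
                      lon = c(1, 2, NA, 4))
  f <- filter_occurrences(mixed)
  expect_equal(f$retained$id, c("a", "d"))
  expect_equal(f$removed$id, c("b", "c"))
})

test_that("records map to half-open cells and counts sum to the total", {
  spec <- grid_spec(0, 2, 0, 2, 1)
  high <- toy_raster(rep(4L, 4), spec)
  rec <- data.frame(id = 1:3, lat = c(0.5, 1.5, 0.2), lon = c(0.5, 1.2, 1.9))
  vc <- occurrence_category_counts(rec, high)
  expect_equal(vc$highly_suitable, 3)
  expect_equal(vc$total, 3)

  # a record exactly on a cell's western/southern edge belongs to that cell
  r4 <- toy_raster(1:4, spec)   # category of cell (1,1) is 1, (2,2) is 4
  edge <- data.frame(id = 1, lat = 1, lon = 1)   # south-west corner of (2,2)
  vc2 <- occurrence_category_counts(edge, r4)
  expect_equal(vc2$highly_suitable, 1)
  # the northern/eastern grid boundary is exclusive
  out <- data.frame(id = 1:2, lat = c(2, 1), lon = c(1, 2))
  vc3 <- occurrence_category_counts(out, r4)
  expect_equal(vc3$out_of_grid, 2)

  set.seed(31)
  spec2 <- grid_spec(5, 10, 5, 10, 0.5)
  r <- toy_raster(sample(1:4, 100, TRUE), spec2)
  rec <- data.frame(id = 1:60,
                    lat = runif(60, 3, 12), lon = runif(60, 3, 12))
  rec$lat[1:4] <- NA
  vc <- occurrence_category_counts(rec, r)
  # brute-force point-in-cell scan
  brute <- numeric(4); oog <- 0
  for (k in 5:60) {
    hit <- FALSE
    for (i in seq_along(spec2$lats)) for (j in seq_along(spec2$lons)) {
      w <- spec2$lons[j] - 0.25; s <- spec2$lats[i] - 0.25
      if (rec$lat[k] >= s && rec$lat[k] < s + 0.5 &&
          rec$lon[k] >= w && rec$lon[k] < w + 0.5) {
        brute[r$category[i, j]] <- brute[r$category[i, j]] + 1
        hit <- TRUE
      }
    }
    if (!hit) oog <- oog + 1
  }
  expect_equal(unname(unlist(vc[1, 1:4])), brute)
  expect_equal(vc$out_of_grid, oog)
  expect_equal(vc$missing_coords, 4)
  expect_equal(vc$unsuitable + vc$marginal + vc$suitable +
                 vc$highly_suitable + vc$no_data + vc$out_of_grid +
                 vc$missing_coords, vc$total)
})
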