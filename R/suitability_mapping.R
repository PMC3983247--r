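#' Area of a latitude/longitude grid cell
#'
#' Spherical band formula on the authalic sphere (R = 6371 km):
#' `R^2 * dlon_rad * (sin(lat + res/2) - sin(lat - res/2))`.
#'
#' @param lat_center Cell-center latitude(s), degrees.
#' @param resolution Cell size in degrees.
#' @return Cell area(s) in km^2.
#' @examples
#' cell_area_km2(0, 0.5)    # ~3091 km^2 on the equator
#' cell_area_km2(60, 0.5)   # ~half of that
#' @export
cell_area_km2 <- function(lat_center, resolution) {
  stop_if_not_number(resolution, "resolution", positive = TRUE)
  if (any(abs(lat_center) + resolution / 2 > 90 + 1e-9))
    stop("cell extends beyond a pole", call. = FALSE)
  r <- 6371
  half <- resolution / 2
  rad <- pi / 180
  r^2 * (resolution * rad) *
    (sin((lat_center + half) * rad) - sin((lat_center - half) * rad))
}

#' Per-category areas of a suitability raster
#'
#' Latitude-aware area accounting: each cell contributes its spherical cell
#' area to its suitability category; no-data cells are excluded from both
#' the categories and the total, so the four categories always sum to the
#' total.
#'
#' @param raster An `ei_raster` from [run_model()].
#' @return A one-row data.frame with columns `unsuitable`, `marginal`,
#'   `suitable`, `highly_suitable`, `total` (km^2).
#' @export
category_areas <- function(raster) {
  stopifnot(inherits(raster, "ei_raster"))
  g <- raster$grid
  cell_area <- matrix(cell_area_km2(g$lats, g$resolution),
                      length(g$lats), length(g$lons))
  out <- as.list(vapply(1:4, function(k) {
    sum(cell_area[!is.na(raster$category) & raster$category == k])
  }, numeric(1)))
  names(out) <- suitability_levels()
  out$total <- sum(cell_area[!is.na(raster$category)])
  as.data.frame(out)
}

#' Category transitions between a baseline and an adjusted run
#'
#' Pairs each cell's baseline category with its adjusted category and
#' tabulates the 4 x 4 transition counts and areas; the diagonal is the
#' unchanged area.  Marginals of the transition table equal each raster's
#' own category totals.
#'
#' @param baseline,adjusted Two `ei_raster` objects on the same grid.
#' @return An object of class `change_map`: `codes` (lat x lon matrix,
#'   `4 * (baseline - 1) + adjusted`, 1-16), `counts` and `areas` (4 x 4
#'   matrices, baseline in rows, adjusted in columns).
#' @export
change_map <- function(baseline, adjusted) {
  stopifnot(inherits(baseline, "ei_raster"), inherits(adjusted, "ei_raster"))
  g <- baseline$grid
  if (!isTRUE(all.equal(g[c("lats", "lons")],
                        adjusted$grid[c("lats", "lons")])))
    stop("rasters are on different grids", call. = FALSE)
  b <- baseline$category; a <- adjusted$category
  cell_area <- matrix(cell_area_km2(g$lats, g$resolution),
                      length(g$lats), length(g$lons))
  lv <- suitability_levels()
  counts <- areas <- matrix(0, 4, 4, dimnames = list(baseline = lv,
                                                     adjusted = lv))
  ok <- !is.na(b) & !is.na(a)
  for (i in 1:4) for (j in 1:4) {
    sel <- ok & b == i & a == j
    counts[i, j] <- sum(sel)
    areas[i, j] <- sum(cell_area[sel])
  }
  codes <- matrix(NA_integer_, nrow(b), ncol(b))
  codes[ok] <- 4L * (b[ok] - 1L) + a[ok]
  structure(list(codes = codes, counts = counts, areas = areas),
            class = "change_map")
}

#' Filter occurrence records lacking coordinates
#'
#' Removes records missing either coordinate, preserving the order of the
#' retained records and logging every removal.
#'
#' @param records A data.frame with columns `id`, `lat`, `lon` (and
#'   optionally `source`).
#' @return A list with `retained` (data.frame), `removed` (data.frame with
#'   an added `reason` column).
#' @export
filter_occurrences <- function(records) {
  stopifnot(is.data.frame(records), all(c("lat", "lon") %in% names(records)))
  miss <- is.na(records$lat) | is.na(records$lon)
  removed <- records[miss, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "missing coordinates"
  else removed$reason <- character()
  list(retained = records[!miss, , drop = FALSE], removed = removed)
}

# Half-open cell assignment [west, east) x [south, north): index along one
# axis, or NA when outside [min, max).
axis_index <- function(x, lo, hi, res, n) {
  i <- floor((x - lo) / res) + 1
  i[x < lo | x >= hi] <- NA_integer_
  as.integer(pmin(i, n))  # guards floating round-off just below `hi`
}

#' Count occurrence records per suitability category
#'
#' Maps each located record to its containing grid cell (cells are treated
#' as half-open `[west, east) x [south, north)`, so a record exactly on a
#' cell's western or southern edge belongs to that cell) and counts records
#' per category; records outside the grid, or in no-data cells, are counted
#' separately, as are records lacking coordinates.
#'
#' @param records A data.frame with columns `lat`, `lon` (records lacking
#'   coordinates are tallied, not dropped).
#' @param raster An `ei_raster`.
#' @return A one-row data.frame: one column per suitability category plus
#'   `no_data`, `out_of_grid`, `missing_coords` and `total`; the columns sum
#'   to `total`.
#' @export
occurrence_category_counts <- function(records, raster) {
  stopifnot(is.data.frame(records), inherits(raster, "ei_raster"))
  g <- raster$grid
  miss <- is.na(records$lat) | is.na(records$lon)
  li <- axis_index(records$lat, g$lat_min, g$lat_max, g$resolution,
                   length(g$lats))
  oi <- axis_index(records$lon, g$lon_min, g$lon_max, g$resolution,
                   length(g$lons))
  li[miss] <- NA_integer_; oi[miss] <- NA_integer_
  out_of_grid <- !miss & (is.na(li) | is.na(oi))
  counts <- stats::setNames(numeric(4), suitability_levels())
  no_data <- 0L
  inside <- which(!miss & !out_of_grid)
  for (k in inside) {
    cat_k <- raster$category[li[k], oi[k]]
    if (is.na(cat_k)) no_data <- no_data + 1L
    else counts[cat_k] <- counts[cat_k] + 1
  }
  out <- as.data.frame(as.list(counts))
  out$no_data <- no_data
  out$out_of_grid <- sum(out_of_grid)
  out$missing_coords <- sum(miss)
  out$total <- nrow(records)
  out
}
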