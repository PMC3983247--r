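#' Define a regular latitude/longitude grid
#'
#' Cell centers are placed at `min + (i - 0.5) * resolution` along each axis,
#' latitude positive north and longitude positive east (WGS84 convention).
#' The number of cells along each axis is `round(extent / resolution)`.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid extent in decimal degrees.
#' @param resolution Cell size in degrees (default 0.5, the resolution of the
#'   global long-term climate normals the generator emulates).
#' @return An object of class `grid_spec` with cell-center coordinate vectors
#'   `lats` (south to north) and `lons` (west to east).
#' @examples
#' g <- grid_spec(25, 40, 44, 64, resolution = 0.5)
#' length(g$lats) * length(g$lons)
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution = 0.5) {
  stop_if_not_number(resolution, "resolution", positive = TRUE)
  if (lat_max <= lat_min) stop("lat_max must be > lat_min", call. = FALSE)
  if (lon_max <= lon_min) stop("lon_max must be > lon_min", call. = FALSE)
  n_lat <- round((lat_max - lat_min) / resolution)
  n_lon <- round((lon_max - lon_min) / resolution)
  if (n_lat < 1 || n_lon < 1)
    stop("degenerate grid: extent smaller than one cell", call. = FALSE)
  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    resolution = resolution,
    lats = lat_min + (seq_len(n_lat) - 0.5) * resolution,
    lons = lon_min + (seq_len(n_lon) - 0.5) * resolution
  ), class = "grid_spec")
}

#' Parameterize a synthetic climate scenario
#'
#' The scenario controls a latitudinal temperature gradient with a seasonal
#' sinusoid (phase inverted in the southern hemisphere), a fixed diurnal
#' half-range separating monthly minimum and maximum temperature from the
#' monthly mean, latitudinal arid/humid precipitation bands with a seasonal
#' profile, and relative humidity derived monotonically from the annual
#' precipitation total.  Identical scenario and seed give bit-identical
#' climate grids.
#'
#' @param equator_temp Mean annual temperature at the equator (degrees C).
#' @param lapse Decrease of mean annual temperature per degree of absolute
#'   latitude (degrees C per degree).
#' @param seasonal_amplitude Half-range of the monthly temperature sinusoid
#'   (degrees C); warmest in July north of the equator, in January south.
#' @param diurnal_half_range Half of the diurnal range: `tmin = tavg - d`,
#'   `tmax = tavg + d` (degrees C, default 6).
#' @param arid_band Absolute-latitude interval `c(lo, hi)` of the arid belt.
#' @param arid_annual_mm,humid_annual_mm Annual precipitation totals (mm)
#'   inside and outside the arid belt.
#' @param band_transition Width (degrees of latitude) of the linear blend
#'   between the arid and humid annual totals at each edge of the belt.
#' @param precip_seasonality Relative amplitude in `[0, 1]` of the monthly
#'   precipitation sinusoid.
#' @param precip_phase `"summer"` for a monsoonal regime (wettest when the
#'   local hemisphere is warmest, the default) or `"winter"` for a
#'   Mediterranean regime.
#' @param noise_sd Standard deviation (degrees C) of cell-wise noise added
#'   once to the annual mean temperature (not per month, so the seasonal
#'   shape stays smooth).
#' @param seed Integer seed controlling the noise.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(equator_temp = 30, lapse = 0.45,
                             seasonal_amplitude = 9, diurnal_half_range = 6,
                             arid_band = c(15, 35),
                             arid_annual_mm = 250, humid_annual_mm = 1000,
                             band_transition = 8,
                             precip_seasonality = 0.7,
                             precip_phase = c("summer", "winter"),
                             noise_sd = 0.5, seed = 1L) {
  for (nm in c("seasonal_amplitude", "diurnal_half_range", "arid_annual_mm",
               "humid_annual_mm", "noise_sd"))
    if (get(nm) < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  if (precip_seasonality < 0 || precip_seasonality > 1)
    stop("`precip_seasonality` must be in [0, 1]", call. = FALSE)
  if (band_transition < 0) stop("`band_transition` must be >= 0", call. = FALSE)
  precip_phase <- match.arg(precip_phase)
  structure(list(
    equator_temp = equator_temp, lapse = lapse,
    seasonal_amplitude = seasonal_amplitude,
    diurnal_half_range = diurnal_half_range,
    arid_band = arid_band,
    arid_annual_mm = arid_annual_mm, humid_annual_mm = humid_annual_mm,
    band_transition = band_transition,
    precip_seasonality = precip_seasonality,
    precip_phase = precip_phase,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "climate_scenario")
}

# Internal constructor; checks the physical invariants of monthly normals.
new_climate_normals <- function(grid, tmin, tmax, precip, rh09, rh15) {
  dims <- c(length(grid$lats), length(grid$lons), 12L)
  for (nm in c("tmin", "tmax", "precip", "rh09", "rh15")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims)))
      stop(sprintf("field `%s` must be a lat x lon x 12 array", nm),
           call. = FALSE)
  }
  ok <- !is.na(tmin) & !is.na(tmax)
  if (any(tmin[ok] > tmax[ok] + 1e-9))
    stop("tmin > tmax in some cell-month", call. = FALSE)
  if (any(precip < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  if (any(rh09 < 0 | rh09 > 100, na.rm = TRUE) ||
      any(rh15 < 0 | rh15 > 100, na.rm = TRUE))
    stop("relative humidity outside [0, 100]", call. = FALSE)
  structure(list(grid = grid, tmin = tmin, tmax = tmax, precip = precip,
                 rh09 = rh09, rh15 = rh15), class = "climate_normals")
}

# month-center phase on a 12-month cycle, m = 1..12
month_phase <- function(m) 2 * pi * (m - 0.5) / 12

#' Generate synthetic monthly climate normals
#'
#' Builds a deterministic, seeded grid of monthly climate normals with the
#' structure of a 0.5-degree global climatology: for each cell, 12 monthly
#' values of minimum and maximum temperature, precipitation and relative
#' humidity at 09:00 and 15:00.  Monthly mean temperature is
#' `equator_temp - lapse * |lat|` plus a seasonal sinusoid (phase inverted
#' south of the equator) plus cell-wise seeded noise; `tmin`/`tmax` sit a
#' fixed diurnal half-range below/above the mean.  Precipitation follows the
#' scenario's arid/humid latitudinal bands with a seasonal profile, and
#' humidity increases monotonically with the annual precipitation total.
#'
#' @param spec A [grid_spec()].
#' @param scenario A [climate_scenario()].
#' @return An object of class `climate_normals`: the grid plus arrays
#'   `tmin`, `tmax`, `precip`, `rh09`, `rh15` of dimension lat x lon x 12.
#' @examples
#' norm <- generate_climate(grid_spec(0, 5, 0, 5, 1), climate_scenario())
#' dim(norm$tmin)
#' @export
generate_climate <- function(spec, scenario) {
  stopifnot(inherits(spec, "grid_spec"), inherits(scenario, "climate_scenario"))
  n_lat <- length(spec$lats); n_lon <- length(spec$lons)
  noise <- with_seed(scenario$seed,
                     matrix(stats::rnorm(n_lat * n_lon, 0, scenario$noise_sd),
                            n_lat, n_lon))
  dims <- c(n_lat, n_lon, 12L)
  tmin <- tmax <- precip <- rh09 <- rh15 <- array(NA_real_, dims)
  hemi <- ifelse(spec$lats >= 0, 1, -1)  # inverts the seasonal phase in the SH
  t_annual <- scenario$equator_temp - scenario$lapse * abs(spec$lats)
  # aridity membership: 1 inside the belt, linear taper to 0 at each edge
  w <- max(scenario$band_transition, 1e-9)
  outside <- pmax(scenario$arid_band[1] - abs(spec$lats),
                  abs(spec$lats) - scenario$arid_band[2])
  aridity <- clamp(1 - pmax(0, outside) / w, 0, 1)
  p_annual <- scenario$humid_annual_mm -
    (scenario$humid_annual_mm - scenario$arid_annual_mm) * aridity
  rh_base <- clamp(30 + 60 * pmin(1, p_annual / 1200), 0, 100)
  for (m in 1:12) {
    seas <- -cos(month_phase(m))          # -1 in January, +1 in July (NH)
    tavg <- outer(t_annual + scenario$seasonal_amplitude * seas * hemi,
                  rep(1, n_lon)) + noise
    tmin[, , m] <- tavg - scenario$diurnal_half_range
    tmax[, , m] <- tavg + scenario$diurnal_half_range
    phase <- if (scenario$precip_phase == "summer") 1 else -1
    pm <- p_annual / 12 * (1 + phase * scenario$precip_seasonality * seas * hemi)
    precip[, , m] <- outer(pmax(0, pm), rep(1, n_lon))
    rh09[, , m] <- outer(rh_base, rep(1, n_lon))
    rh15[, , m] <- outer(clamp(rh_base - 12, 0, 100), rep(1, n_lon))
  }
  new_climate_normals(spec, tmin, tmax, precip, rh09, rh15)
}

# Build normals from an explicit per-cell monthly mean temperature matrix
# [n_lat x 12] (same for all longitudes) and a monthly precipitation matrix,
# used by the engineered single-axis scenarios below.
normals_from_profiles <- function(spec, tavg_by_lat, precip_by_lat,
                                  diurnal_half_range, rh = 50) {
  n_lat <- length(spec$lats); n_lon <- length(spec$lons)
  dims <- c(n_lat, n_lon, 12L)
  tmin <- tmax <- precip <- rh09 <- rh15 <- array(NA_real_, dims)
  for (m in 1:12) {
    tmin[, , m] <- outer(tavg_by_lat[, m] - diurnal_half_range, rep(1, n_lon))
    tmax[, , m] <- outer(tavg_by_lat[, m] + diurnal_half_range, rep(1, n_lon))
    precip[, , m] <- outer(precip_by_lat[, m], rep(1, n_lon))
    rh09[, , m] <- rh
    rh15[, , m] <- max(0, rh - 12)
  }
  new_climate_normals(spec, tmin, tmax, precip, rh09, rh15)
}

# Month lengths of a 365-day climatological year.
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# Monthly precipitation (mm/month) that steers the bucket model along a
# prescribed monthly storage path `path` (fractions of capacity), given the
# monthly mean temperature `tavg_m` of the cell.  Months where `path` is NA
# get zero precipitation (a full-deficit reset that drives storage to zero
# regardless of its previous state).  The storage-changing part of the
# precipitation is divided by the month's week-attribution factor (the
# number of week midpoints falling in the month times 7 / days-in-month),
# so the weekly series delivers the prescribed change exactly.
precip_for_storage_path <- function(path, tavg_m, bucket) {
  wpm <- tabulate(month_of_day(week_midpoints()), nbins = 12)
  attribution <- wpm * 7 / MONTH_DAYS
  evap <- bucket$evap_coeff * pmax(0, tavg_m) * MONTH_DAYS / 7
  p <- numeric(12)
  prev <- 0
  for (m in 1:12) {
    if (is.na(path[m])) { p[m] <- 0; prev <- 0 }
    else {
      p[m] <- max(0, evap[m] +
                    bucket$capacity * (path[m] - prev) / attribution[m])
      prev <- path[m]
    }
  }
  p
}

#' Engineered climate in which only temperature limits growth
#'
#' Constructs climate normals for parameter-recovery testing in which the
#' temperature axis is the only limiting one.  Monthly mean temperature
#' spans roughly 6.5-38.5 degrees C across latitude and season, so all four
#' temperature knots of the growth response bind somewhere on the grid (the
#' limiting high knot through the slope of the upper ramp), while zero
#' diurnal range keeps weekly minima above every cold-stress threshold
#' level and maxima below every heat-stress threshold level.  Precipitation
#' is scheduled so the converged soil-moisture cycle is either exactly zero
#' (a winter full-deficit reset) or inside the moisture plateau common to
#' all design levels, with every transition week stepping over the dry
#' ramps; moisture and stress parameters therefore have no effect at any of
#' their design levels.  The growing season is moisture-gated to about 19
#' weeks, which places the warm and cold grid edges near the suitability
#' boundary where temperature-knot changes move the suitable area.
#'
#' @param spec A [grid_spec()].
#' @param bucket Bucket parameters used to schedule precipitation; pass the
#'   same object to [run_model()] or [execute_design()].
#' @return A `climate_normals` object (deterministic; no noise).
#' @export
climate_temperature_limited <- function(spec, bucket = bucket_parameters()) {
  n_lat <- length(spec$lats)
  frac <- (spec$lats - spec$lat_min) / (spec$lat_max - spec$lat_min)
  t_center <- 36 - 26 * frac            # warmest at the southern edge
  tavg <- outer(t_center, rep(1, 12)) +
    outer(rep(-3.5, n_lat), cos(month_phase(1:12)))
  # storage path: plateau May-September, stepped descent that lands at 0.04
  # (above the dry ramps), then a full-deficit clamp to zero over winter
  path <- c(NA, NA, NA, NA, 0.35, 0.35, 0.35, 0.35, 0.12, 0.04, NA, NA)
  precip <- t(vapply(seq_len(n_lat),
                     function(i) precip_for_storage_path(path, tavg[i, ], bucket),
                     numeric(12)))
  normals_from_profiles(spec, tavg, precip, diurnal_half_range = 0, rh = 45)
}

#' Engineered climate in which only soil moisture limits growth
#'
#' The mirror image of [climate_temperature_limited()]: monthly mean
#' temperature is a constant 28 degrees C (inside the optimal plateau for
#' every temperature-knot design level, with a 5 degree diurnal half-range
#' keeping extremes away from all stress thresholds), while a latitudinal
#' wetness gradient drives a short moisture pulse (an exactly-attributed
#' February rise, a March hold, then a single-week evaporative collapse)
#' whose peak sweeps from the dry ramp (0.005-0.02 of bucket capacity)
#' through the plateau up to 0.58, probing all four moisture knots -- the
#' upper two through the peak weeks, the lower two through the dry rows --
#' while never reaching any wet-stress threshold level.  The short pulse
#' keeps the probed rows near the suitability boundary so moisture-knot
#' changes move the suitable area.
#'
#' @inheritParams climate_temperature_limited
#' @param bucket Bucket parameters; the default uses a higher evaporative
#'   demand (2.1 mm per degree C per week) so the pulse collapses within one
#'   week.  Pass the same object to [run_model()] or [execute_design()].
#' @return A `climate_normals` object (deterministic; no noise).
#' @export
climate_moisture_limited <- function(spec,
                                     bucket = bucket_parameters(evap_coeff = 2.1)) {
  n_lat <- length(spec$lats)
  frac <- (spec$lats - spec$lat_min) / (spec$lat_max - spec$lat_min)
  # peak storage by latitude band: upper-knot probe, dry-ramp probe,
  # plateau anchor, bare
  peak <- vapply(frac, function(f) {
    if (f < 0.25) 0.58
    else if (f < 0.55) exp(log(0.02) + (log(0.005) - log(0.02)) *
                             (f - 0.25) / 0.30)
    else if (f < 0.80) 0.30
    else 0
  }, numeric(1))
  tavg <- matrix(28, n_lat, 12)
  precip <- t(vapply(seq_len(n_lat), function(i) {
    path <- c(NA, peak[i], peak[i], NA, NA, NA, NA, NA, NA, NA, NA, NA)
    precip_for_storage_path(path, tavg[i, ], bucket)
  }, numeric(12)))
  normals_from_profiles(spec, tavg, precip, diurnal_half_range = 5, rh = 60)
}

#' Generate a synthetic occurrence-record fixture
#'
#' Draws `n_total` occurrence records, of which exactly `n_missing_coords`
#' lack geographical coordinates; the remainder fall uniformly inside the
#' grid extent.  Deterministic under `seed`.  The packaged default fixture
#' uses 145 records with 19 lacking coordinates, matching the structure of a
#' typical multi-source compilation (database records plus literature
#' records without georeferencing).
#'
#' @param n_total Total number of records (>= 0).
#' @param n_missing_coords Number of records without coordinates
#'   (`<= n_total`).
#' @param spec A [grid_spec()] giving the extent for the located records.
#' @param seed Integer seed.
#' @return A data.frame with columns `id`, `lat`, `lon`, `source`; missing
#'   coordinates are `NA`.
#' @export
generate_occurrences <- function(n_total, n_missing_coords, spec, seed = 1L) {
  if (n_total < 0 || n_missing_coords < 0)
    stop("record counts must be non-negative", call. = FALSE)
  if (n_missing_coords > n_total)
    stop("n_missing_coords must be <= n_total", call. = FALSE)
  if (n_total == 0)
    return(data.frame(id = character(), lat = numeric(), lon = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  with_seed(as.integer(seed), {
    lat <- stats::runif(n_total, spec$lat_min, spec$lat_max)
    lon <- stats::runif(n_total, spec$lon_min, spec$lon_max)
    src <- sample(c("GBIF", "MBG", "literature", "survey"), n_total,
                  replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1))
    drop <- if (n_missing_coords > 0) sample.int(n_total, n_missing_coords)
            else integer()
    lat[drop] <- NA_real_; lon[drop] <- NA_real_
    data.frame(id = sprintf("occ-%03d", seq_len(n_total)),
               lat = lat, lon = lon, source = src, stringsAsFactors = FALSE)
  })
}
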