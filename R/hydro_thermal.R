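#' Bucket water-balance parameters
#'
#' A single-store soil water balance: weekly storage gains rainfall and loses
#' a temperature-scaled evaporative demand, clamped between empty and a
#' maximum storage above field capacity that represents waterlogged soil.
#' Storage is expressed as a fraction of `capacity`, so the species'
#' moisture knots (SM0-SM3, given as fractions) apply directly.
#'
#' @param capacity Bucket capacity in mm (default 100).
#' @param evap_coeff Evaporative demand per degree of above-zero weekly mean
#'   temperature (mm per degree C per week, default 0.8).
#' @param max_fraction Upper clamp on storage as a multiple of capacity
#'   (default 2.5, allowing waterlogged states above field capacity).
#' @return An object of class `bucket_parameters`.
#' @export
bucket_parameters <- function(capacity = 100, evap_coeff = 0.8,
                              max_fraction = 2.5) {
  stop_if_not_number(capacity, "capacity", positive = TRUE)
  stop_if_not_number(evap_coeff, "evap_coeff")
  stop_if_not_number(max_fraction, "max_fraction", positive = TRUE)
  if (evap_coeff < 0) stop("`evap_coeff` must be >= 0", call. = FALSE)
  structure(list(capacity = capacity, evap_coeff = evap_coeff,
                 max_fraction = max_fraction), class = "bucket_parameters")
}

# Week midpoints (day of a 365-day year).  The weekly calendar is a fixed
# 52 x 7-day (364-day) year; midpoints are rescaled onto the 365-day
# climatological calendar that carries the monthly normals.
week_midpoints <- function() (3.5 + 7 * (0:51)) * 365 / 364

month_midpoints <- function() cumsum(MONTH_DAYS) - MONTH_DAYS / 2

# Month containing each day-of-year (vectorized).
month_of_day <- function(day) {
  findInterval(day, c(0, cumsum(MONTH_DAYS)), rightmost.closed = TRUE)
}

# Cyclic linear interpolation of 12 monthly values (matrix cells x 12) at
# the 52 week midpoints; returns cells x 52.
interp_monthly <- function(x, wd = week_midpoints()) {
  mid <- month_midpoints()
  # pad with December (shifted back a year) and January (shifted forward)
  mid_ext <- c(mid[12] - 365, mid, mid[1] + 365)
  x_ext <- cbind(x[, 12, drop = FALSE], x, x[, 1, drop = FALSE])
  iv <- findInterval(wd, mid_ext)               # interval index per week
  w <- (wd - mid_ext[iv]) / (mid_ext[iv + 1] - mid_ext[iv])
  x_ext[, iv, drop = FALSE] * rep(1 - w, each = nrow(x)) +
    x_ext[, iv + 1, drop = FALSE] * rep(w, each = nrow(x))
}

#' Convert monthly climate normals to a 52-week series
#'
#' Temperatures are linearly interpolated between successive month midpoints
#' (cyclically over the year) and evaluated at week midpoints (week `w` has
#' midpoint day `3.5 + 7 (w - 1)` of a 364-day year, rescaled to the 365-day
#' monthly calendar).  Weekly precipitation is the midpoint month's total
#' times `7 / days-in-month`, which conserves the annual total to within a
#' few percent.  The weekly mean is the midpoint of the interpolated
#' extremes, so `tmin_w <= tavg_w <= tmax_w` by construction.
#'
#' @param normals A `climate_normals` object.
#' @return An object of class `weekly_climate`: the grid plus matrices
#'   `tmin_w`, `tmax_w`, `tavg_w`, `precip_w` of dimension cells x 52, where
#'   cells are in column-major (lat-fastest) order of the grid.
#' @export
monthly_to_weekly <- function(normals) {
  stopifnot(inherits(normals, "climate_normals"))
  n_lat <- length(normals$grid$lats); n_lon <- length(normals$grid$lons)
  ncell <- n_lat * n_lon
  as_mat <- function(a) matrix(a, ncell, 12)   # cells x 12
  wd <- week_midpoints()
  tmin_w <- interp_monthly(as_mat(normals$tmin), wd)
  tmax_w <- interp_monthly(as_mat(normals$tmax), wd)
  m_of_w <- month_of_day(wd)
  pmon <- as_mat(normals$precip)
  precip_w <- pmon[, m_of_w, drop = FALSE] *
    rep(7 / MONTH_DAYS[m_of_w], each = ncell)
  structure(list(grid = normals$grid,
                 tmin_w = tmin_w, tmax_w = tmax_w,
                 tavg_w = (tmin_w + tmax_w) / 2,
                 precip_w = precip_w),
            class = "weekly_climate")
}

#' Weekly soil-moisture series from a bucket water balance
#'
#' Iterates the storage recursion
#' `sm_w = clamp(sm_(w-1) + (precip_w - E_w) / capacity, 0, max_fraction)`
#' with evaporative demand `E_w = evap_coeff * max(0, tavg_w)`, cycling over
#' the 52-week year from an initial storage of 0.5 until the annual cycle is
#' a fixed point (successive cycles within 1e-6) or 20 cycles have run.
#' The result is deterministic and, for forcing with a contracting phase
#' (any week that clamps), independent of the initial storage.
#'
#' @param weekly A `weekly_climate` object.
#' @param bucket A [bucket_parameters()] object.
#' @return An object of class `soil_moisture_series`: the grid, a cells x 52
#'   matrix `sm_w` of storage fractions, the bucket parameters, and the
#'   attained cycle-to-cycle sup-norm difference `converged_delta`.
#' @export
soil_moisture_series <- function(weekly, bucket = bucket_parameters()) {
  stopifnot(inherits(weekly, "weekly_climate"),
            inherits(bucket, "bucket_parameters"))
  ncell <- nrow(weekly$precip_w)
  gain <- (weekly$precip_w -
             bucket$evap_coeff * pmax(0, weekly$tavg_w)) / bucket$capacity
  sm <- matrix(NA_real_, ncell, 52)
  state <- rep(0.5, ncell)
  delta <- Inf
  for (cycle in 1:20) {
    prev <- sm
    for (w in 1:52) {
      state <- clamp(state + gain[, w], 0, bucket$max_fraction)
      sm[, w] <- state
    }
    delta <- if (cycle > 1) max(abs(sm - prev), na.rm = TRUE) else Inf
    if (is.finite(delta) && delta < 1e-6) break
  }
  structure(list(grid = weekly$grid, sm_w = sm, bucket = bucket,
                 converged_delta = delta),
            class = "soil_moisture_series")
}
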