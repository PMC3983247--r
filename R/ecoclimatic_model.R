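#' Species parameters of the ecoclimatic model
#'
#' The fourteen parameters describing a species' climatic response: four
#' temperature knots (degrees C) and four soil-moisture knots (fractions of
#' bucket capacity) defining trapezoidal growth responses, plus three
#' stress threshold/rate pairs (cold, heat, wet).  Defaults are the fitted
#' values for date palm (*Phoenix dactylifera*): a hot-arid crop with a wide
#' thermal plateau (20-39 degrees C), tolerance of very dry soil
#' (SM0 = 0.007) and sensitivity to waterlogging (SMWS = 0.9).
#'
#' @param DV0,DV1,DV2,DV3 Limiting low, lower optimal, upper optimal and
#'   limiting high temperature (degrees C); must satisfy
#'   `DV0 < DV1 <= DV2 < DV3`.
#' @param SM0,SM1,SM2,SM3 Limiting low, lower optimal, upper optimal and
#'   limiting high soil moisture (fractions); `SM0 < SM1 <= SM2 < SM3`.
#' @param TTCS Cold-stress temperature threshold (degrees C), applied to the
#'   weekly minimum temperature.
#' @param THCS Cold-stress accumulation rate per week; stored signed
#'   (negative as conventionally printed) but applied by magnitude.
#' @param TTHS Heat-stress temperature threshold (degrees C), applied to the
#'   weekly maximum temperature.
#' @param THHS Heat-stress accumulation rate per week (>= 0).
#' @param SMWS Wet-stress soil-moisture threshold (fraction).
#' @param HWS Wet-stress accumulation rate per week (>= 0).
#' @return An object of class `species_parameters` (a validated named list).
#' @examples
#' p <- species_parameters()       # date-palm defaults
#' p$DV2
#' @export
species_parameters <- function(DV0 = 14, DV1 = 20, DV2 = 39, DV3 = 46,
                               SM0 = 0.007, SM1 = 0.013, SM2 = 0.81, SM3 = 0.9,
                               TTCS = 4, THCS = -0.01, TTHS = 46, THHS = 0.9,
                               SMWS = 0.9, HWS = 0.022) {
  p <- list(DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3,
            SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
            TTCS = TTCS, THCS = THCS, TTHS = TTHS, THHS = THHS,
            SMWS = SMWS, HWS = HWS)
  validate_species_parameters(p)
}

#' @rdname species_parameters
#' @param p A named list with the fourteen parameter codes.
#' @export
validate_species_parameters <- function(p) {
  codes <- parameter_codes()
  missing <- setdiff(codes, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in codes) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter %s must be a single finite number", nm),
           call. = FALSE)
    p[[nm]] <- as.numeric(unname(v))
  }
  check_order <- function(lo, hi, strict = TRUE) {
    bad <- if (strict) p[[lo]] >= p[[hi]] else p[[lo]] > p[[hi]]
    if (bad)
      stop(sprintf("ordering violation: %s (%g) must be %s %s (%g)",
                   lo, p[[lo]], if (strict) "<" else "<=", hi, p[[hi]]),
           call. = FALSE)
  }
  check_order("DV0", "DV1"); check_order("DV1", "DV2", strict = FALSE)
  check_order("DV2", "DV3")
  check_order("SM0", "SM1"); check_order("SM1", "SM2", strict = FALSE)
  check_order("SM2", "SM3")
  if (p$THCS > 0) stop("THCS must be <= 0 (printed as a negative rate)",
                       call. = FALSE)
  if (p$THHS < 0) stop("THHS must be >= 0", call. = FALSE)
  if (p$HWS < 0) stop("HWS must be >= 0", call. = FALSE)
  structure(p[codes], class = "species_parameters")
}

#' @rdname species_parameters
#' @export
parameter_codes <- function() {
  c("DV0", "DV1", "DV2", "DV3", "SM0", "SM1", "SM2", "SM3",
    "TTCS", "THCS", "TTHS", "THHS", "SMWS", "HWS")
}

# Trapezoidal 0-1 response over knots k0 < k1 <= k2 < k3: 0 at/below k0 and
# at/above k3, 1 on [k1, k2], linear on the ramps.  Continuous everywhere.
trapezoid <- function(x, k0, k1, k2, k3) {
  up <- (x - k0) / (k1 - k0)
  down <- (k3 - x) / (k3 - k2)
  clamp(pmin(up, down), 0, 1)
}

#' Weekly temperature and moisture growth indices
#'
#' Trapezoidal responses: zero at or beyond the limiting knots, one on the
#' optimal plateau, linear on the ramps between.
#'
#' @param tavg_w Weekly mean temperature(s), degrees C (any shape).
#' @param sm_w Weekly soil-moisture fraction(s) (any shape).
#' @param p A [species_parameters()] object.
#' @return Values in `[0, 1]`, same shape as the input.
#' @examples
#' temperature_index(c(17, 25, 46), species_parameters())
#' @export
temperature_index <- function(tavg_w, p) {
  stopifnot(inherits(p, "species_parameters"))
  trapezoid(tavg_w, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' @rdname temperature_index
#' @export
moisture_index <- function(sm_w, p) {
  stopifnot(inherits(p, "species_parameters"))
  trapezoid(sm_w, p$SM0, p$SM1, p$SM2, p$SM3)
}

#' Annual growth index
#'
#' The weekly growth index is the product of the temperature and moisture
#' indices; its mean over the 52 weeks is the annual growth index.
#'
#' @param ti,mi Weekly temperature and moisture indices: vectors of length
#'   52, or cells x 52 matrices.
#' @return The annual growth index in `[0, 1]` (scalar, or one value per
#'   row for matrix input).
#' @export
growth_index_annual <- function(ti, mi) {
  if (is.matrix(ti) || is.matrix(mi)) {
    stopifnot(is.matrix(ti), is.matrix(mi), identical(dim(ti), dim(mi)),
              ncol(ti) == 52)
    return(rowMeans(ti * mi))
  }
  if (length(ti) != 52 || length(mi) != 52)
    stop("weekly index series must have length 52", call. = FALSE)
  mean(ti * mi)
}

#' Accumulate an annual stress index from weekly threshold exceedances
#'
#' Weekly increments are `|rate| * exceedance_w`, weighted by the number of
#' consecutive stress weeks up to and including the current one (the counter
#' resets on any stress-free week), so that accumulation grows superlinearly
#' with stress duration; the annual sum is capped at 1, the point at which
#' the species cannot persist.
#'
#' @param exceedance Non-negative weekly exceedances (degrees or moisture
#'   units beyond the threshold): a length-52 vector or a cells x 52 matrix.
#' @param rate Weekly accumulation rate; its magnitude is used.
#' @return Stress index in `[0, 1]` (scalar or one value per row).
#' @examples
#' accumulate_stress(c(1, rep(0, 51)), 0.01)  # one isolated stress week
#' @export
accumulate_stress <- function(exceedance, rate) {
  x <- if (is.matrix(exceedance)) exceedance else matrix(exceedance, 1)
  if (ncol(x) != 52)
    stop("exceedance series must have 52 weeks", call. = FALSE)
  if (any(x < 0, na.rm = TRUE))
    stop("exceedances must be non-negative", call. = FALSE)
  k <- numeric(nrow(x))
  s <- numeric(nrow(x))
  for (w in 1:52) {
    stressed <- !is.na(x[, w]) & x[, w] > 0
    k <- ifelse(stressed, k + 1, 0)
    s <- s + abs(rate) * x[, w] * k
  }
  s[apply(x, 1, anyNA)] <- NA_real_
  out <- pmin(1, s)
  if (is.matrix(exceedance)) out else out[1]
}

#' Ecoclimatic Index
#'
#' Combines the annual growth index with the annual cold, heat and wet
#' stress indices into the 0-100 suitability score
#' `EI = 100 * GI_A * (1 - CS) * (1 - HS) * (1 - WS)`.  Any stress reaching
#' 1 forces EI to 0: the species cannot persist.
#'
#' @param gi_a Annual growth index in `[0, 1]`.
#' @param cs,hs,ws Cold, heat and wet stress indices in `[0, 1]`.
#' @return EI in `[0, 100]` (vectorized).
#' @export
ecoclimatic_index <- function(gi_a, cs = 0, hs = 0, ws = 0) {
  for (v in list(gi_a, cs, hs, ws))
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      stop("all inputs to ecoclimatic_index must lie in [0, 1]", call. = FALSE)
  100 * gi_a * (1 - cs) * (1 - hs) * (1 - ws)
}

#' Suitability categories
#'
#' `EI = 0` is unsuitable; `0 < EI < 10` marginal; `10 <= EI < 20` suitable;
#' `EI >= 20` highly suitable.  The boundaries at 10 and 20 belong to the
#' upper category (half-open intervals).
#'
#' @param ei Ecoclimatic Index values in `[0, 100]`.
#' @return A factor with levels `unsuitable`, `marginal`, `suitable`,
#'   `highly_suitable` (shape preserved for matrix input via the underlying
#'   integer codes; see [run_model()]).
#' @export
classify_ei <- function(ei) {
  if (any(ei < 0 | ei > 100, na.rm = TRUE))
    stop("EI must lie in [0, 100]", call. = FALSE)
  codes <- ifelse(is.na(ei), NA_integer_,
                  ifelse(ei <= 0, 1L,
                         ifelse(ei < 10, 2L, ifelse(ei < 20, 3L, 4L))))
  factor(suitability_levels()[codes], levels = suitability_levels())
}

#' @rdname classify_ei
#' @export
suitability_levels <- function() {
  c("unsuitable", "marginal", "suitable", "highly_suitable")
}

#' Run the ecoclimatic model on a climate grid
#'
#' Composes the full per-cell pipeline: monthly-to-weekly conversion, bucket
#' soil-moisture balance, weekly trapezoidal growth indices, annual stress
#' accumulation (cold stress on weekly minima below TTCS, heat stress on
#' weekly maxima above TTHS, wet stress on soil moisture above SMWS) and the
#' Ecoclimatic Index with its four-way classification.  Cells with missing
#' climate propagate as no-data and are excluded from classification.
#'
#' @param normals A `climate_normals` object.
#' @param p A [species_parameters()] object.
#' @param bucket A [bucket_parameters()] object.
#' @return An object of class `ei_raster`: the grid plus lat x lon matrices
#'   `ei`, `category` (integer codes 1-4 matching [suitability_levels()]),
#'   `gi_a`, `cs`, `hs`, `ws`.
#' @examples
#' norm <- generate_climate(grid_spec(20, 30, 40, 50, 2), climate_scenario())
#' r <- run_model(norm, species_parameters())
#' table(suitability_levels()[r$category])
#' @export
run_model <- function(normals, p = species_parameters(),
                      bucket = bucket_parameters()) {
  stopifnot(inherits(normals, "climate_normals"),
            inherits(p, "species_parameters"))
  weekly <- monthly_to_weekly(normals)
  sm <- soil_moisture_series(weekly, bucket)
  ti <- temperature_index(weekly$tavg_w, p)
  mi <- moisture_index(sm$sm_w, p)
  gi_a <- growth_index_annual(ti, mi)
  cs <- accumulate_stress(pmax(p$TTCS - weekly$tmin_w, 0), p$THCS)
  hs <- accumulate_stress(pmax(weekly$tmax_w - p$TTHS, 0), p$THHS)
  ws <- accumulate_stress(pmax(sm$sm_w - p$SMWS, 0), p$HWS)
  ei <- ecoclimatic_index(gi_a, cs, hs, ws)
  n_lat <- length(normals$grid$lats); n_lon <- length(normals$grid$lons)
  shape <- function(x) matrix(x, n_lat, n_lon)
  category <- matrix(as.integer(classify_ei(ei)), n_lat, n_lon)
  structure(list(grid = normals$grid, ei = shape(ei), category = category,
                 gi_a = shape(gi_a), cs = shape(cs), hs = shape(hs),
                 ws = shape(ws), parameters = p),
            class = "ei_raster")
}
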