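# Independent straight-line scalar oracle for the full per-cell pipeline,
# written with explicit loops and its own interpolation/bookkeeping so it
# shares no code path with the package implementation.

oracle_month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# EI (plus components) for a single cell from its 12 monthly values.
scalar_ei_oracle <- function(tmin_m, tmax_m, precip_m, p, bucket) {
  md <- oracle_month_days
  mend <- cumsum(md)
  mmid <- mend - md / 2

  tmin_w <- tmax_w <- tavg_w <- precip_w <- numeric(52)
  for (w in 1:52) {
    d <- (3.5 + 7 * (w - 1)) * 365 / 364
    # cyclic linear interpolation between month midpoints
    if (d < mmid[1]) {
      lo <- 12; hi <- 1; span <- (mmid[1] + 365) - mmid[12]
      f <- (d + 365 - mmid[12]) / span
    } else if (d >= mmid[12]) {
      lo <- 12; hi <- 1; span <- (mmid[1] + 365) - mmid[12]
      f <- (d - mmid[12]) / span
    } else {
      lo <- max(which(mmid <= d)); hi <- lo + 1
      f <- (d - mmid[lo]) / (mmid[hi] - mmid[lo])
    }
    tmin_w[w] <- tmin_m[lo] * (1 - f) + tmin_m[hi] * f
    tmax_w[w] <- tmax_m[lo] * (1 - f) + tmax_m[hi] * f
    tavg_w[w] <- (tmin_w[w] + tmax_w[w]) / 2
    m <- min(which(d <= mend))
    precip_w[w] <- precip_m[m] * 7 / md[m]
  }

  sm <- numeric(52)
  state <- 0.5
  prev <- rep(Inf, 52)
  for (cycle in 1:20) {
    for (w in 1:52) {
      e <- bucket$evap_coeff * max(0, tavg_w[w])
      state <- state + (precip_w[w] - e) / bucket$capacity
      state <- min(max(state, 0), bucket$max_fraction)
      sm[w] <- state
    }
    if (max(abs(sm - prev)) < 1e-6) break
    prev <- sm
  }

  trap <- function(x, k0, k1, k2, k3) {
    if (x <= k0 || x >= k3) return(0)
    if (x >= k1 && x <= k2) return(1)
    if (x < k1) (x - k0) / (k1 - k0) else (k3 - x) / (k3 - k2)
  }
  gi <- 0
  for (w in 1:52)
    gi <- gi + trap(tavg_w[w], p$DV0, p$DV1, p$DV2, p$DV3) *
      trap(sm[w], p$SM0, p$SM1, p$SM2, p$SM3)
  gi <- gi / 52

  stress <- function(exc, rate) {
    s <- 0; k <- 0
    for (w in 1:52) {
      if (exc[w] > 0) k <- k + 1 else k <- 0
      s <- s + abs(rate) * exc[w] * k
    }
    min(1, s)
  }
  cs <- stress(pmax(0, p$TTCS - tmin_w), p$THCS)
  hs <- stress(pmax(0, tmax_w - p$TTHS), p$THHS)
  ws <- stress(pmax(0, sm - p$SMWS), p$HWS)

  list(ei = 100 * gi * (1 - cs) * (1 - hs) * (1 - ws),
       gi_a = gi, cs = cs, hs = hs, ws = ws, sm = sm, tavg_w = tavg_w)
}

# Build climate normals directly from per-cell monthly fields.
make_normals <- function(spec, tmin, tmax, precip, rh09 = NULL, rh15 = NULL) {
  dims <- c(length(spec$lats), length(spec$lons), 12L)
  full <- function(x) if (is.array(x) && length(dim(x)) == 3) x else
    array(x, dims)
  if (is.null(rh09)) rh09 <- array(50, dims)
  if (is.null(rh15)) rh15 <- array(40, dims)
  ecoclimex:::new_climate_normals(spec, full(tmin), full(tmax), full(precip),
                                  full(rh09), full(rh15))
}

# Uniform-climate helper: every cell-month identical.
uniform_normals <- function(spec, tavg, diurnal = 5, precip = 80) {
  make_normals(spec, tavg - diurnal, tavg + diurnal, precip)
}

# Minimal weekly_climate object from explicit weekly series (single cell or
# matrix input), for driving the soil-moisture recursion directly.
make_weekly <- function(tavg_w, precip_w, grid = grid_spec(0, 1, 0, 1, 1)) {
  tavg_w <- if (is.matrix(tavg_w)) tavg_w else matrix(tavg_w, 1)
  precip_w <- if (is.matrix(precip_w)) precip_w else matrix(precip_w, 1)
  structure(list(grid = grid, tmin_w = tavg_w, tmax_w = tavg_w,
                 tavg_w = tavg_w, precip_w = precip_w),
            class = "weekly_climate")
}

# Random valid species parameters (knots drawn and sorted with margins).
random_parameters <- function() {
  dv <- sort(stats::runif(4, 0, 45) + c(0, 1, 1, 2) * 0.5)
  dv <- dv + c(0, 0.5, 0.6, 1.2)
  sm <- sort(stats::runif(4, 0.001, 1.2))
  sm <- sm + c(0, 0.01, 0.012, 0.025)
  species_parameters(DV0 = dv[1], DV1 = dv[2], DV2 = dv[3], DV3 = dv[4],
                     SM0 = sm[1], SM1 = sm[2], SM2 = sm[3], SM3 = sm[4],
                     TTCS = stats::runif(1, -5, 8),
                     THCS = -stats::runif(1, 0, 0.05),
                     TTHS = stats::runif(1, 35, 50),
                     THHS = stats::runif(1, 0, 1),
                     SMWS = stats::runif(1, 0.5, 1.5),
                     HWS = stats::runif(1, 0, 0.05))
}
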