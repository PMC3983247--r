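#' Construct the mixed-level L54 orthogonal array
#'
#' Builds the 54-run mixed-level orthogonal array L54(2^1 x 3^25): column 1
#' takes two levels (27 runs each), columns 2-26 take three levels (18 runs
#' each), and every pair of three-level columns is strength-2 balanced (each
#' of the 9 level pairs occurs exactly 6 times).
#'
#' The construction is of Addelman-Kempthorne type over GF(3): runs are
#' indexed by a half indicator `z` and a vector `y` in GF(3)^3; thirteen
#' columns are linear forms `a . y` (plus a half-dependent constant) and
#' twelve are quadratic columns `b . y + y1^2` whose quadratic term flips
#' sign in the second half (with a small linear/constant correction), which
#' makes the quadratic Gauss-sum defects of the two halves cancel exactly.
#' The correction constants were found by exhaustive search over each plane
#' through the `y1` axis; the result is validated structurally by
#' [validate_orthogonal_array()].
#'
#' @return A 54 x 26 integer matrix; column 1 in `1:2`, columns 2-26 in
#'   `1:3`.
#' @export
oa54_mixed <- function() {
  runs <- expand.grid(y3 = 0:2, y2 = 0:2, y1 = 0:2, z = 0:1)
  lin <- function(a, gamma) {
    ((a[1] * runs$y1 + a[2] * runs$y2 + a[3] * runs$y3) + gamma * runs$z) %% 3
  }
  quad <- function(b, mu, delta) {
    h0 <- (b[1] * runs$y1 + b[2] * runs$y2 + b[3] * runs$y3 + runs$y1^2) %% 3
    h1 <- ((b[1] + mu) * runs$y1 + b[2] * runs$y2 + b[3] * runs$y3 -
             runs$y1^2 + delta) %% 3
    ifelse(runs$z == 0, h0, h1)
  }
  gam <- c(0, 0, 1); del <- c(2, 2, 1); mu <- c(1, 2, 0)
  planes <- list(c(1, 0), c(0, 1), c(1, 1), c(1, 2))
  cols <- list(lin(c(1, 0, 0), 0))
  for (p in planes) for (cc in 0:2)
    cols[[length(cols) + 1]] <- lin(c(cc, p[1], p[2]), gam[cc + 1])
  for (p in planes) for (cc in 0:2)
    cols[[length(cols) + 1]] <- quad(c(cc, p[1], p[2]), mu[cc + 1], del[cc + 1])
  a <- cbind(runs$z, do.call(cbind, cols)) + 1L
  storage.mode(a) <- "integer"
  dimnames(a) <- list(NULL, c("c1", paste0("c", 2:26)))
  a
}

#' Validate the structure of a mixed-level L54 array
#'
#' Checks all orthogonal-array invariants exhaustively: 54 rows, 26 columns;
#' the two-level column holds each level 27 times; every three-level column
#' holds each level 18 times; every pair of three-level columns shows each
#' of the 9 level pairs exactly 6 times; and the two-level column pairs with
#' every three-level column 9 times per combination.
#'
#' @param array A 54 x 26 matrix.
#' @return The array, invisibly; errors describe the first violation found.
#' @export
validate_orthogonal_array <- function(array) {
  if (!is.matrix(array) || nrow(array) != 54 || ncol(array) != 26)
    stop("orthogonal array must be 54 x 26", call. = FALSE)
  if (!all(array[, 1] %in% 1:2) ||
      !all(table(factor(array[, 1], 1:2)) == 27))
    stop("two-level column is not balanced 27/27", call. = FALSE)
  for (j in 2:26) {
    if (!all(array[, j] %in% 1:3) ||
        !all(table(factor(array[, j], 1:3)) == 18))
      stop(sprintf("three-level column %d is not balanced 18/18/18", j),
           call. = FALSE)
    if (!all(table(array[, 1], array[, j]) == 9))
      stop(sprintf("columns 1 and %d violate mixed-level balance", j),
           call. = FALSE)
  }
  for (i in 2:25) for (j in (i + 1):26)
    if (!all(table(array[, i], array[, j]) == 6))
      stop(sprintf("columns %d and %d violate strength-2 balance", i, j),
           call. = FALSE)
  invisible(array)
}

#' Load the packaged L54 orthogonal-array fixture
#'
#' Reads the canonical L54(2^1 x 3^25) array shipped with the package as a
#' CSV fixture and validates every structural invariant at load, signalling
#' a corrupted fixture otherwise.
#'
#' @param path Path to the array CSV (default: the packaged fixture).
#' @return A validated 54 x 26 integer matrix.
#' @export
load_orthogonal_array <- function(path = system.file("extdata", "oa54.csv",
                                                     package = "ecoclimex")) {
  if (!nzchar(path) || !file.exists(path))
    stop("orthogonal-array fixture not found", call. = FALSE)
  a <- as.matrix(utils::read.csv(path))
  storage.mode(a) <- "integer"
  validate_orthogonal_array(a)
  a
}

#' The packaged factor-level table for the sensitivity analysis
#'
#' Fourteen factors (the fourteen species parameters) each at three levels;
#' level 2 of every factor is the baseline date-palm value, levels 1 and 3
#' bracket it.
#'
#' @param path Path to a CSV with columns `factor`, `level1`-`level3`
#'   (default: the packaged table).
#' @return A data.frame of class `factor_table`.
#' @export
read_factor_table <- function(path = system.file("extdata",
                                                 "factor_levels.csv",
                                                 package = "ecoclimex")) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_factor_table(ft)
}

#' @rdname read_factor_table
#' @param ft A data.frame with columns `factor`, `level1`, `level2`,
#'   `level3`.
#' @export
validate_factor_table <- function(ft) {
  need <- c("factor", "level1", "level2", "level3")
  if (!all(need %in% names(ft)))
    stop("factor table needs columns factor, level1, level2, level3",
         call. = FALSE)
  if (anyDuplicated(ft$factor)) stop("duplicate factors", call. = FALSE)
  unknown <- setdiff(ft$factor, parameter_codes())
  if (length(unknown))
    stop("unknown factor code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(ft, class = c("factor_table", "data.frame"))
}

# Enforce the knot-ordering invariants on a raw parameter list by clamping
# the upper knot of a violated pair to the lower knot + 0.1 (a degenerate
# ramp).  Returns the repaired list plus a log of repairs.
repair_parameters <- function(raw) {
  log <- data.frame(knot = character(), from = numeric(), to = numeric(),
                    stringsAsFactors = FALSE)
  fix <- function(lo, hi, strict) {
    bad <- if (strict) raw[[hi]] <= raw[[lo]] else raw[[hi]] < raw[[lo]]
    if (bad) {
      log[nrow(log) + 1L, ] <<- list(hi, raw[[hi]], raw[[lo]] + 0.1)
      raw[[hi]] <<- raw[[lo]] + 0.1
    }
  }
  fix("DV0", "DV1", strict = TRUE)
  fix("DV1", "DV2", strict = FALSE)
  fix("DV2", "DV3", strict = TRUE)
  fix("SM0", "SM1", strict = TRUE)
  fix("SM1", "SM2", strict = FALSE)
  fix("SM2", "SM3", strict = TRUE)
  if (raw$THCS > 0) {
    log[nrow(log) + 1L, ] <- list("THCS", raw$THCS, -abs(raw$THCS))
    raw$THCS <- -abs(raw$THCS)
  }
  list(parameters = validate_species_parameters(raw), log = log)
}

#' Build a Taguchi design over the species parameters
#'
#' Assigns each factor to one of the 25 three-level array columns (the
#' two-level column and the remaining three-level columns stay unassigned)
#' and materializes one complete parameter set per run.  The default
#' allocation follows linear-graph practice: the four temperature knots and
#' the four moisture knots are placed on column families whose within-family
#' interaction contrasts fall only on unassigned columns, so the
#' knot-pair interactions inherent in trapezoidal responses (a ramp's slope
#' depends on both of its knots) cannot masquerade as main effects of
#' unrelated factors.  Level combinations that violate the knot-ordering
#' invariants (e.g. an upper-optimal temperature above the limiting high
#' temperature) are repaired by clamping the upper knot to the lower
#' knot + 0.1, and every repair is logged.
#'
#' @param array An L54 array from [load_orthogonal_array()] or
#'   [oa54_mixed()].
#' @param factors A factor table from [read_factor_table()].
#' @param columns Integer vector, one three-level column index (1-25) per
#'   factor; the default is the interaction-protected allocation for the
#'   packaged fourteen-factor table, or the first `n` three-level columns
#'   for other factor tables.
#' @return An object of class `taguchi_design`: the array, the factor
#'   table, `columns`, `levels` (runs x factors matrix of level indices),
#'   `values` (runs x factors matrix of raw level values), `parameters`
#'   (list of repaired [species_parameters()] per run) and `repairs`
#'   (data.frame with columns `run`, `knot`, `from`, `to`).
#' @export
build_design <- function(array = load_orthogonal_array(),
                         factors = read_factor_table(),
                         columns = default_columns(factors)) {
  factors <- validate_factor_table(factors)
  n_fac <- nrow(factors)
  if (n_fac > ncol(array) - 1)
    stop("more factors than available three-level columns", call. = FALSE)
  if (length(columns) != n_fac || anyDuplicated(columns) ||
      any(columns < 1 | columns > ncol(array) - 1))
    stop("`columns` must be distinct three-level column indices, one per factor",
         call. = FALSE)
  lev <- array[, 1 + columns, drop = FALSE]
  colnames(lev) <- factors$factor
  vals <- matrix(NA_real_, nrow(array), n_fac,
                 dimnames = list(NULL, factors$factor))
  for (f in seq_len(n_fac)) {
    lv <- as.numeric(factors[f, c("level1", "level2", "level3")])
    vals[, f] <- lv[lev[, f]]
  }
  base <- species_parameters()
  params <- vector("list", nrow(array))
  repairs <- data.frame(run = integer(), knot = character(),
                        from = numeric(), to = numeric(),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(array))) {
    raw <- unclass(base)
    for (f in factors$factor) raw[[f]] <- vals[r, f]
    rep_r <- repair_parameters(raw)
    params[[r]] <- rep_r$parameters
    if (nrow(rep_r$log))
      repairs <- rbind(repairs, cbind(run = r, rep_r$log))
  }
  structure(list(array = array, factors = factors, columns = columns,
                 levels = lev, values = vals, parameters = params,
                 repairs = repairs),
            class = "taguchi_design")
}

#' @rdname build_design
#' @export
default_columns <- function(factors) {
  alloc <- c(SM0 = 5L, SM1 = 6L, SM2 = 7L, SM3 = 17L,
             DV0 = 2L, DV1 = 3L, DV2 = 4L, DV3 = 14L,
             TTCS = 8L, THCS = 9L, TTHS = 10L, THHS = 11L,
             SMWS = 12L, HWS = 13L)
  if (all(factors$factor %in% names(alloc)) && !anyDuplicated(factors$factor))
    unname(alloc[factors$factor])
  else
    seq_len(nrow(factors))
}

#' Larger-the-better signal-to-noise ratio
#'
#' `SN = -10 log10( mean(1 / y^2) )` in decibels; with a single replicate
#' this reduces to `20 log10(y)`.  Undefined for non-positive responses.
#'
#' @param y Positive response value(s) of one run.
#' @return The SN ratio in dB.
#' @examples
#' sn_larger_better(1)        # 0 dB
#' sn_larger_better(c(10, 10))  # 20 dB
#' @export
sn_larger_better <- function(y) {
  if (length(y) == 0 || any(!is.finite(y)) || any(y <= 0))
    stop("larger-the-better SN requires positive responses", call. = FALSE)
  -10 * log10(mean(1 / y^2))
}

#' Execute every run of a Taguchi design
#'
#' Runs the ecoclimatic model once per design row (the model is
#' deterministic, so a single replicate per run) on a fixed climate, and
#' takes as the response the combined area of the suitable and highly
#' suitable categories in km^2.  Runs with zero response are floored to
#' 1 km^2 before the SN transform (and flagged), which keeps the transform
#' defined without distorting ranks.
#'
#' @param design A [build_design()] result.
#' @param normals A `climate_normals` object (the same climate for every
#'   run).
#' @param bucket A [bucket_parameters()] object.
#' @return An object of class `taguchi_results`: a data.frame with one row
#'   per run (`run`, the four category areas, `response`, `floored`, `sn`),
#'   carrying the design as attribute `design`.
#' @export
execute_design <- function(design, normals, bucket = bucket_parameters()) {
  stopifnot(inherits(design, "taguchi_design"),
            inherits(normals, "climate_normals"))
  n <- length(design$parameters)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    res <- tryCatch(
      run_model(normals, design$parameters[[r]], bucket),
      error = function(e) stop(sprintf("run %d failed: %s", r,
                                       conditionMessage(e)), call. = FALSE))
    areas <- category_areas(res)
    y <- areas$suitable + areas$highly_suitable
    floored <- y <= 0
    if (floored) y <- 1
    rows[[r]] <- data.frame(run = r,
                            unsuitable = areas$unsuitable,
                            marginal = areas$marginal,
                            suitable = areas$suitable,
                            highly_suitable = areas$highly_suitable,
                            response = y, floored = floored,
                            sn = sn_larger_better(y))
  }
  out <- do.call(rbind, rows)
  attr(out, "design") <- design
  class(out) <- c("taguchi_results", "data.frame")
  out
}

#' Main effects, sensitivity deltas and ranks
#'
#' For every factor, the mean SN ratio over the runs at each of its three
#' levels (18 runs each, by column balance); the sensitivity delta is the
#' range of the three level means, factors are ranked by delta (1 = most
#' sensitive, ties broken by factor-table order), and the optimum level is
#' the one with the highest mean SN.  A factor's optimum is flagged as
#' agreeing with the baseline when it is the level whose value equals the
#' baseline parameter value.
#'
#' @param design A [build_design()] result.
#' @param results An [execute_design()] result (one SN per run).
#' @return An object of class `sensitivity_report`: a data.frame with one
#'   row per factor (`factor`, `sn_level1`-`sn_level3`, `delta`, `rank`,
#'   `opt_level`, `baseline_level`, `baseline_agreement`, `n_floored`).
#' @export
main_effects <- function(design, results) {
  stopifnot(inherits(design, "taguchi_design"))
  if (nrow(results) != nrow(design$levels) ||
      !identical(results$run, seq_len(nrow(design$levels))))
    stop("results must contain one SN per design run, in order",
         call. = FALSE)
  base <- species_parameters()
  fac <- design$factors
  out <- data.frame(factor = fac$factor, sn_level1 = NA_real_,
                    sn_level2 = NA_real_, sn_level3 = NA_real_,
                    stringsAsFactors = FALSE)
  for (f in seq_len(nrow(fac))) {
    for (l in 1:3)
      out[f, paste0("sn_level", l)] <-
        mean(results$sn[design$levels[, f] == l])
  }
  means <- as.matrix(out[, c("sn_level1", "sn_level2", "sn_level3")])
  out$delta <- apply(means, 1, max) - apply(means, 1, min)
  out$rank <- rank(-out$delta, ties.method = "first")
  out$opt_level <- apply(means, 1, which.max)
  out$baseline_level <- vapply(seq_len(nrow(fac)), function(f) {
    lv <- as.numeric(fac[f, c("level1", "level2", "level3")])
    hit <- which(abs(lv - base[[fac$factor[f]]]) < 1e-9)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  out$baseline_agreement <- out$opt_level == out$baseline_level
  out$n_floored <- sum(results$floored)
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Per-factor level-mean series for sensitivity line plots
#'
#' @param report A [main_effects()] report.
#' @return A long data.frame (`factor`, `level`, `sn_mean`) ordered by
#'   factor and level; a flat series corresponds to delta ~ 0.
#' @export
sensitivity_plot_data <- function(report) {
  stopifnot(inherits(report, "sensitivity_report"))
  out <- data.frame(
    factor = rep(report$factor, each = 3),
    level = rep(1:3, times = nrow(report)),
    sn_mean = as.vector(t(as.matrix(
      report[, c("sn_level1", "sn_level2", "sn_level3")]))),
    stringsAsFactors = FALSE)
  out
}
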