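# File I/O: flat key=value parameter files, occurrence CSVs and long-format
# climate/raster CSVs.  Flat parameter files diff cleanly across sensitivity
# runs; CSVs use '.' as decimal separator and UTF-8 regardless of locale.

#' Read and write species-parameter files
#'
#' Flat `key=value` text files using the fourteen parameter codes
#' (`DV0` ... `HWS`), one per line; ordering invariants are validated on
#' read and unknown or missing keys are rejected.
#'
#' @param path File path.
#' @return For the reader, a [species_parameters()] object; the writer
#'   returns `path` invisibly.
#' @export
read_species_parameters <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad))
    stop("malformed line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, character(1), 2))))
  unknown <- setdiff(keys, parameter_codes())
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyNA(vals))
    stop("non-numeric value for: ", paste(keys[is.na(vals)], collapse = ", "),
         call. = FALSE)
  validate_species_parameters(as.list(stats::setNames(vals, keys)))
}

#' @rdname read_species_parameters
#' @param p A [species_parameters()] object.
#' @export
write_species_parameters <- function(p, path) {
  stopifnot(inherits(p, "species_parameters"))
  writeLines(sprintf("%s=%.15g", names(p), unlist(p)), path)
  invisible(path)
}

#' Read and write occurrence CSVs
#'
#' Columns `id,lat,lon,source`; missing coordinates are encoded as empty
#' fields.  Malformed coordinate fields are reported with their line number
#' and the row is skipped.
#'
#' @param path File path.
#' @return For the reader, a data.frame with columns `id`, `lat`, `lon`,
#'   `source`.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "lat", "lon")
  if (!all(need %in% names(raw)))
    stop("occurrence CSV needs columns id, lat, lon", call. = FALSE)
  if (!"source" %in% names(raw)) raw$source <- ""
  num <- function(x) suppressWarnings(as.numeric(x))
  lat <- num(raw$lat); lon <- num(raw$lon)
  malformed <- (nzchar(trimws(raw$lat)) & is.na(lat)) |
    (nzchar(trimws(raw$lon)) & is.na(lon))
  if (any(malformed))
    warning("skipping malformed row(s) at line(s): ",
            paste(which(malformed) + 1L, collapse = ", "), call. = FALSE)
  ok <- !malformed
  data.frame(id = raw$id[ok], lat = lat[ok], lon = lon[ok],
             source = raw$source[ok], stringsAsFactors = FALSE)
}

#' @rdname read_occurrences
#' @param records A data.frame with columns `id`, `lat`, `lon`, `source`.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write climate normals as long-format CSV
#'
#' One row per cell-month with columns
#' `lat,lon,month,tmin,tmax,precip,rh09,rh15`.  The reader reconstructs the
#' grid from the unique coordinates (which must form a complete regular
#' grid) and validates the physical invariants.
#'
#' @param normals A `climate_normals` object.
#' @param path File path.
#' @return For the reader, a `climate_normals` object.
#' @export
write_climate_csv <- function(normals, path) {
  stopifnot(inherits(normals, "climate_normals"))
  g <- normals$grid
  idx <- expand.grid(lat = g$lats, lon = g$lons, month = 1:12)
  df <- data.frame(idx,
                   tmin = as.vector(normals$tmin),
                   tmax = as.vector(normals$tmax),
                   precip = as.vector(normals$precip),
                   rh09 = as.vector(normals$rh09),
                   rh15 = as.vector(normals$rh15))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path)
  lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  res_lat <- diff(lats); res_lon <- diff(lons)
  res <- stats::median(c(res_lat, res_lon))
  if (nrow(df) != length(lats) * length(lons) * 12)
    stop("climate CSV does not cover a complete lat x lon x 12 grid",
         call. = FALSE)
  spec <- grid_spec(min(lats) - res / 2, max(lats) + res / 2,
                    min(lons) - res / 2, max(lons) + res / 2, res)
  o <- order(df$month, match(df$lon, lons), match(df$lat, lats))
  dims <- c(length(lats), length(lons), 12L)
  shape <- function(v) array(v[o], dims)
  new_climate_normals(spec, shape(df$tmin), shape(df$tmax), shape(df$precip),
                      shape(df$rh09), shape(df$rh15))
}

#' Write a suitability raster as long-format CSV
#'
#' One row per cell: `lat,lon,ei,category` (category by name; no-data cells
#' have empty fields).
#'
#' @param raster An `ei_raster`.
#' @param path File path.
#' @export
write_ei_csv <- function(raster, path) {
  stopifnot(inherits(raster, "ei_raster"))
  g <- raster$grid
  idx <- expand.grid(lat = g$lats, lon = g$lons)
  df <- data.frame(idx, ei = as.vector(raster$ei),
                   category = suitability_levels()[as.vector(raster$category)])
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
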