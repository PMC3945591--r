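# Lightweight geographic raster model: WGS84 degrees, origin at the top-left
# corner, row 0 northernmost, row-major storage, square cells. Nodata is
# represented internally as NA; the file sentinel lives in the spec.

#' Grid specification
#'
#' Describes the geometry of a geographic raster: dimensions, square cell
#' size in decimal degrees, and the position of the top-left (north-west)
#' corner. Rows run north to south.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in decimal degrees (square cells).
#' @param origin_lon,origin_lat Longitude / latitude of the top-left corner
#'   of the top-left cell, in degrees.
#' @param nodata Sentinel value used when writing files. Internally nodata
#'   cells are `NA`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_lon = 0, origin_lat = 90, nodata = -9999) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, cell_size > 0)
  if (origin_lat - n_rows * cell_size < -90 - 1e-9)
    stop("grid extends south of -90 degrees latitude")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size = as.numeric(cell_size),
                 origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

spec_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol
}

stop_if_spec_mismatch <- function(a, b, what = "rasters") {
  if (!spec_equal(a, b))
    stop(sprintf("grid specs of %s do not match", what))
  invisible(TRUE)
}

#' Raster layer
#'
#' A matrix of values bound to a [grid_spec()]. `NA` entries are nodata.
#'
#' @param values Numeric matrix with `n_rows` rows and `n_cols` columns
#'   (a scalar or vector is recycled into that shape, row-major).
#' @param spec A [grid_spec()].
#' @return An object of class `hx_raster`: a list with elements `spec` and
#'   `values`.
#' @export
hx_raster <- function(values, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.matrix(values)) {
    values <- matrix(as.numeric(values), nrow = spec$n_rows,
                     ncol = spec$n_cols, byrow = TRUE)
  }
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values shape does not match the grid spec")
  storage.mode(values) <- "double"
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values are not allowed (use NA for nodata)")
  structure(list(spec = spec, values = values), class = "hx_raster")
}

#' @export
print.hx_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("hx_raster [%d x %d] range [%s, %s], %d nodata cells\n",
              nrow(v), ncol(v),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @return `cell_center_lats()` gives the latitude of each row's cell
#'   centres (length `n_rows`, north to south); `cell_center_lons()` the
#'   longitude of each column's centres (length `n_cols`, west to east).
#' @export
cell_center_lats <- function(spec) {
  spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
}

#' @rdname cell_center_lats
#' @export
cell_center_lons <- function(spec) {
  spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
}

# -- ESRI ASCII grid I/O ------------------------------------------------------
# The only raster file format supported is the ESRI ASCII grid (.asc), a
# plain-text header of six key/value lines followed by n_rows lines of
# whitespace-separated values, north row first. GeoTIFF is rejected with an
# informative error: no GDAL-backed reader is available in this build.

#' Read a raster file
#'
#' Reads an ESRI ASCII grid (`.asc`/`.txt`). The header must use
#' `xllcorner`/`yllcorner` (an unrotated, square-cell georeference);
#' `NODATA_value` cells become `NA`.
#'
#' @param path Path to the file.
#' @param band Band number; ASCII grids are single-band so only 1 is valid.
#' @return An [hx_raster()].
#' @export
read_raster <- function(path, band = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF is not supported in this build; use ESRI ASCII grids (.asc)")
  if (band != 1L) stop("ASCII grids are single-band; band must be 1")
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_hdr <- n_hdr + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    miss <- setdiff(need, names(hdr))
    if (any(c("xllcenter", "yllcenter") %in% names(hdr)))
      stop("cell-centre registered ASCII grids are not supported")
    stop("not a valid ESRI ASCII grid (missing header fields: ",
         paste(miss, collapse = ", "), ")")
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  spec <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                    origin_lon = hdr$xllcorner,
                    origin_lat = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    nodata = nodata)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != spec$n_rows * spec$n_cols)
    stop("ASCII grid body has wrong number of values")
  m <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  m[abs(m - nodata) < 1e-12] <- NA_real_
  hx_raster(m, spec)
}

#' Write a raster file
#'
#' Writes an ESRI ASCII grid. Integer-valued layers are written without a
#' decimal point so they round-trip bit-compatibly through [read_raster()].
#'
#' @param r An [hx_raster()].
#' @param path Output path; the parent directory must exist.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "hx_raster"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  s <- r$spec
  v <- r$values
  v[is.na(v)] <- s$nodata
  integral <- all(v == round(v))
  fmt <- function(x) {
    if (integral) sprintf("%.0f", x) else format(x, digits = 17, trim = TRUE,
                                                 scientific = FALSE)
  }
  hdr <- c(sprintf("ncols %d", s$n_cols),
           sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.10g", s$origin_lon),
           sprintf("yllcorner %.10g", s$origin_lat - s$n_rows * s$cell_size),
           sprintf("cellsize %.10g", s$cell_size),
           sprintf("NODATA_value %.10g", s$nodata))
  body <- apply(v, 1L, function(row) paste(fmt(row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Nearest-neighbour resampling
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's centre; centres falling outside the source extent become nodata.
#' Values are never interpolated, so categorical layers (deciles, zone ids)
#' are safe to resample.
#'
#' @param src An [hx_raster()].
#' @param target A [grid_spec()] that geographically overlaps `src`.
#' @return An [hx_raster()] on `target`.
#' @export
resample_nearest <- function(src, target) {
  stopifnot(inherits(src, "hx_raster"), inherits(target, "grid_spec"))
  s <- src$spec
  # extents: [W, E] x [S, N]
  s_e <- s$origin_lon + s$n_cols * s$cell_size
  s_s <- s$origin_lat - s$n_rows * s$cell_size
  t_e <- target$origin_lon + target$n_cols * target$cell_size
  t_s <- target$origin_lat - target$n_rows * target$cell_size
  if (s$origin_lon >= t_e || target$origin_lon >= s_e ||
      s_s >= target$origin_lat || t_s >= s$origin_lat)
    stop("source and target extents are disjoint")
  lons <- cell_center_lons(target)
  lats <- cell_center_lats(target)
  col_idx <- floor((lons - s$origin_lon) / s$cell_size) + 1L
  row_idx <- floor((s$origin_lat - lats) / s$cell_size) + 1L
  col_idx[col_idx < 1L | col_idx > s$n_cols] <- NA_integer_
  row_idx[row_idx < 1L | row_idx > s$n_rows] <- NA_integer_
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  ok_r <- which(!is.na(row_idx))
  ok_c <- which(!is.na(col_idx))
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- src$values[row_idx[ok_r], col_idx[ok_c], drop = FALSE]
  hx_raster(out, target)
}

#' Cell areas on the sphere
#'
#' Area of each cell in km2 on a sphere of authalic radius 6371.0 km:
#' `(R * d) * (R * d * cos(lat))` with `d` the cell size in radians and
#' `lat` the cell-centre latitude. Constant along a row, shrinking toward
#' the poles.
#'
#' @param spec A [grid_spec()].
#' @return An [hx_raster()] of areas (km2).
#' @export
cell_areas <- function(spec) {
  R <- 6371.0
  d <- spec$cell_size * pi / 180
  lat <- cell_center_lats(spec) * pi / 180
  row_area <- (R * d) * (R * d * cos(lat))
  hx_raster(matrix(row_area, spec$n_rows, spec$n_cols, byrow = FALSE), spec)
}

#' Zonal sum
#'
#' Sums raster values over the cells of each zone (country). Nodata value
#' cells contribute 0; cells with no zone id are ignored. Zones with no
#' cells are absent from the result.
#'
#' @param values An [hx_raster()] of values to accumulate.
#' @param zones An [hx_raster()] of integer zone ids on the same spec
#'   (`NA` = unassigned/ocean).
#' @return A data frame with columns `zone_id` and `sum`, sorted by zone id.
#' @export
zonal_sum <- function(values, zones) {
  stopifnot(inherits(values, "hx_raster"), inherits(zones, "hx_raster"))
  stop_if_spec_mismatch(values$spec, zones$spec, "values and zones")
  v <- values$values
  v[is.na(v)] <- 0
  z <- zones$values
  keep <- !is.na(z)
  if (!any(keep)) return(data.frame(zone_id = integer(0), sum = numeric(0)))
  s <- tapply(v[keep], as.integer(z[keep]), sum)
  data.frame(zone_id = as.integer(names(s)), sum = as.numeric(s),
             row.names = NULL)
}

# great-circle distance in km between (lon1, lat1) and vectors (lon2, lat2)
haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}
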