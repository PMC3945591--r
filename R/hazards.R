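# Hazard frequency construction: event records -> per-cell event counts ->
# relative-frequency deciles -> hazard weights H in {0, 0.1, ..., 1.0}.
# One tally per event per cell, never per track point or per flood day.

#' Default cyclone buffer radii
#'
#' Great-circle buffer radius (km) applied around every track point, by
#' storm intensity category 1-6 (Saffir-Simpson-style classes). The
#' published wind-field extents behind the original hazard grids are not
#' reproducible, so buffers are a configurable per-category stand-in.
#'
#' @export
default_cyclone_radii <- c(`1` = 50, `2` = 100, `3` = 150,
                           `4` = 200, `5` = 250, `6` = 300)

#' Cyclone event frequency grid
#'
#' Counts, per cell, the number of cyclone events whose buffered track
#' covers the cell centre. A track covers a cell if any of its points lies
#' within the category's buffer radius (great-circle distance). A cell is
#' tallied at most once per event, however many track points pass over it.
#'
#' @param tracks Data frame of track points with columns `event_id`,
#'   `point_index`, `lon`, `lat`, `category` (category constant within an
#'   event). Zero rows give an all-zero grid.
#' @param spec Target [grid_spec()].
#' @param radii_km Named vector mapping category to buffer radius in km;
#'   must be positive and non-decreasing in category.
#' @return An [hx_raster()] of non-negative integer counts.
#' @export
cyclone_frequency <- function(tracks, spec, radii_km = default_cyclone_radii) {
  stopifnot(inherits(spec, "grid_spec"))
  if (any(radii_km <= 0) || is.unsorted(radii_km))
    stop("buffer radii must be positive and non-decreasing in category")
  counts <- matrix(0, spec$n_rows, spec$n_cols)
  if (is.null(tracks) || nrow(tracks) == 0L) return(hx_raster(counts, spec))
  need <- c("event_id", "lon", "lat", "category")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns event_id, lon, lat, category")
  if (!all(as.character(tracks$category) %in% names(radii_km)))
    stop("unknown cyclone category: ",
         paste(setdiff(unique(as.character(tracks$category)),
                       names(radii_km)), collapse = ", "))
  lons <- cell_center_lons(spec)
  lats <- cell_center_lats(spec)
  km_per_deg <- 6371.0 * pi / 180          # meridional degree length
  for (ev in split(tracks, tracks$event_id)) {
    radius <- radii_km[[as.character(ev$category[1])]]
    covered <- matrix(FALSE, spec$n_rows, spec$n_cols)
    for (i in seq_len(nrow(ev))) {
      p_lon <- ev$lon[i]; p_lat <- ev$lat[i]
      # candidate window: generous bounding box around the buffer
      dlat <- radius / km_per_deg
      rows <- which(abs(lats - p_lat) <= dlat + spec$cell_size)
      if (!length(rows)) next
      coslat <- max(cos(p_lat * pi / 180), 1e-6)
      dlon <- radius / (km_per_deg * coslat)
      cols <- which(abs(lons - p_lon) <= dlon + spec$cell_size)
      if (!length(cols)) next
      for (r in rows) {
        d <- haversine_km(p_lon, p_lat, lons[cols], lats[r])
        covered[r, cols[d <= radius]] <- TRUE
      }
    }
    counts <- counts + covered
  }
  hx_raster(counts, spec)
}

#' Flood event frequency grid
#'
#' Counts, per cell, the number of flood events whose footprint box contains
#' the cell centre — a count of inundation events, not of inundated days.
#' Footprints are degree-snapped bounding boxes.
#'
#' @param events Data frame with columns `event_id`, `lon_min`, `lat_min`,
#'   `lon_max`, `lat_max` (corners in whole degrees). Zero rows give an
#'   all-zero grid.
#' @param spec Target [grid_spec()].
#' @return An [hx_raster()] of non-negative integer counts.
#' @export
flood_frequency <- function(events, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  counts <- matrix(0, spec$n_rows, spec$n_cols)
  if (is.null(events) || nrow(events) == 0L) return(hx_raster(counts, spec))
  if (any(events$lon_max <= events$lon_min | events$lat_max <= events$lat_min))
    stop("degenerate flood footprint (zero-area box)")
  lons <- cell_center_lons(spec)
  lats <- cell_center_lats(spec)
  for (i in seq_len(nrow(events))) {
    rows <- which(lats >= events$lat_min[i] & lats <= events$lat_max[i])
    cols <- which(lons >= events$lon_min[i] & lons <= events$lon_max[i])
    if (length(rows) && length(cols))
      counts[rows, cols] <- counts[rows, cols] + 1
  }
  hx_raster(counts, spec)
}

#' Detect drought events in one monthly precipitation series
#'
#' A month qualifies when its calendar month's long-term median is at least
#' `min_median_mm` and precipitation is at most 50% of that median. A
#' drought event is a maximal run of three or more consecutive qualifying
#' months; the event count is the number of such runs.
#'
#' The `min_median_mm` floor prevents hyper-arid cells (median near zero)
#' from qualifying perpetually through `0 <= 0.5 * 0` — such cells register
#' little or no drought, mirroring the behaviour of anomaly-based drought
#' definitions in water-scarce regions.
#'
#' @param series Numeric vector of monthly precipitation (mm), length >= 3.
#' @param medians Per-calendar-month long-term medians (length 12, January
#'   first), or `NULL` to compute them from `series`.
#' @param min_median_mm Minimum median (mm) for a month to be eligible.
#' @param start_month Calendar month (1-12) of `series[1]`.
#' @return Integer count of drought events.
#' @export
detect_drought_events <- function(series, medians = NULL, min_median_mm = 1,
                                  start_month = 1L) {
  if (length(series) < 3L) stop("precipitation series shorter than 3 months")
  if (any(series < 0, na.rm = TRUE)) stop("negative precipitation")
  cal <- ((start_month - 1L + seq_along(series) - 1L) %% 12L) + 1L
  if (is.null(medians)) {
    medians <- vapply(1:12, function(m) {
      x <- series[cal == m]
      if (length(x)) stats::median(x) else NA_real_
    }, numeric(1))
  }
  med <- medians[cal]
  qualifies <- !is.na(med) & med >= min_median_mm & series <= 0.5 * med
  r <- rle(qualifies)
  sum(r$values & r$lengths >= 3L)
}

#' Monthly precipitation cube
#'
#' A stack of monthly precipitation layers on one (typically coarse) grid.
#'
#' @param values Array `n_rows x n_cols x n_months` of precipitation (mm),
#'   `n_months >= 36`.
#' @param spec The cube's [grid_spec()].
#' @param start_month Calendar month (1-12) of the first layer.
#' @return An object of class `precip_cube`.
#' @export
precip_cube <- function(values, spec, start_month = 1L) {
  stopifnot(inherits(spec, "grid_spec"), length(dim(values)) == 3L)
  if (dim(values)[1] != spec$n_rows || dim(values)[2] != spec$n_cols)
    stop("cube shape does not match the grid spec")
  if (dim(values)[3] < 36L)
    stop("precipitation cube must span at least 36 months")
  if (any(values < 0, na.rm = TRUE)) stop("negative precipitation")
  structure(list(spec = spec, values = values,
                 start_month = as.integer(start_month)),
            class = "precip_cube")
}

#' Drought event frequency grid
#'
#' Applies [detect_drought_events()] to every cell's monthly series.
#'
#' @param cube A [precip_cube()].
#' @param min_median_mm Minimum eligible monthly median (mm).
#' @return An [hx_raster()] of event counts on the cube's grid.
#' @export
drought_frequency <- function(cube, min_median_mm = 1) {
  stopifnot(inherits(cube, "precip_cube"))
  s <- cube$spec
  counts <- matrix(0, s$n_rows, s$n_cols)
  for (r in seq_len(s$n_rows)) {
    for (cc in seq_len(s$n_cols)) {
      counts[r, cc] <- detect_drought_events(
        cube$values[r, cc, ], min_median_mm = min_median_mm,
        start_month = cube$start_month)
    }
  }
  hx_raster(counts, s)
}

#' Valid-cell mask for the decile sort
#'
#' A cell enters the hazard-frequency ranking when its population density is
#' at least `density_threshold` persons per km2 OR it carries significant
#' agriculture; cells failing both are excluded (sparsely populated,
#' non-agricultural land does not dilute the relative-frequency deciles).
#'
#' @param pop Population counts ([hx_raster()], persons per cell).
#' @param areas Cell areas from [cell_areas()] (km2).
#' @param agriculture 0/1 [hx_raster()] flagging significant agriculture.
#' @param density_threshold Density cutoff in persons per km2; a cell with
#'   density strictly below it and no agriculture is excluded.
#' @return Logical matrix, `TRUE` for valid cells.
#' @export
valid_cell_mask <- function(pop, areas, agriculture, density_threshold = 5) {
  stop_if_spec_mismatch(pop$spec, areas$spec, "pop and areas")
  stop_if_spec_mismatch(pop$spec, agriculture$spec, "pop and agriculture")
  p <- pop$values
  p[is.na(p)] <- 0
  ag <- agriculture$values
  ag[is.na(ag)] <- 0
  (p / areas$values >= density_threshold) | (ag == 1)
}

#' Relative-frequency deciles
#'
#' Sorts the valid cells with at least one event into deciles 1-10 of their
#' event counts. Boundaries are the nearest-rank 10th..90th percentiles of
#' the positive valid counts; a cell's decile is one plus the number of
#' boundaries strictly below its count, so equal counts always share a
#' decile. Invalid or zero-count cells get decile 0 ("no hazard"). If every
#' positive count is identical the ranking is degenerate and all those cells
#' are placed in the top decile.
#'
#' @param freq Frequency [hx_raster()] of event counts.
#' @param mask Logical validity matrix from [valid_cell_mask()] (or `NULL`
#'   to treat every cell as valid).
#' @return An [hx_raster()] of deciles in 0..10.
#' @export
to_deciles <- function(freq, mask = NULL) {
  stopifnot(inherits(freq, "hx_raster"))
  v <- freq$values
  v[is.na(v)] <- 0
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  if (!identical(dim(mask), dim(v)))
    stop("mask shape does not match the frequency grid")
  pos <- mask & v > 0
  out <- matrix(0, nrow(v), ncol(v))
  if (any(pos)) {
    counts <- v[pos]
    if (length(unique(counts)) == 1L) {
      out[pos] <- 10
    } else {
      srt <- sort(counts)
      n <- length(srt)
      bounds <- srt[ceiling((1:9) / 10 * n)]   # nearest-rank percentiles
      out[pos] <- 1 + vapply(counts, function(x) sum(bounds < x), numeric(1))
    }
  }
  hx_raster(out, freq$spec)
}

#' Decile-to-weight mapping
#'
#' Hazard event likelihood H = decile / 10, so decile 10 maps to 1.0 (the
#' anchor for the theoretical maximum country score) and decile 0 stays 0.
#'
#' @param d Decile [hx_raster()] with values in 0..10.
#' @return An [hx_raster()] of weights in \{0, 0.1, ..., 1.0\}.
#' @export
decile_weights <- function(d) {
  stopifnot(inherits(d, "hx_raster"))
  v <- d$values
  if (any(!is.na(v) & (v < 0 | v > 10 | v != round(v))))
    stop("deciles must be integers in 0..10")
  v[is.na(v)] <- 0
  hx_raster(v / 10, d$spec)
}
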