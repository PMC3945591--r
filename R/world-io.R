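# On-disk representation of a world: the same plain-text formats the
# pipeline reads, so synthetic inputs and real datasets are interchangeable
# stage inputs.
#
#   population.asc, zones.asc, agriculture.asc   ESRI ASCII grids
#   zones_legend.csv                             zone_id, iso3, name
#   cyclone_tracks.csv                           event_id, point_index,
#                                                lon, lat, category
#   flood_events.csv                             event_id, lon_min, lat_min,
#                                                lon_max, lat_max
#   precip_cube.csv                              row, col, m1..mM (mm)
#   precip_months.csv                            band, year, month
#   precip_meta.json                             cube grid spec, start month
#   urban_fractions.csv                          country_id, proportion_urban
#   hdi_classes.csv                              country_id, hdi_class
#   truth.json                                   generator ground truth

#' Write a world's input files
#'
#' @param world A world list from [generate_world()] or
#'   [make_extreme_country_fixture()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(world$population, file.path(dir, "population.asc"))
  write_raster(world$zones, file.path(dir, "zones.asc"))
  write_raster(world$agriculture, file.path(dir, "agriculture.asc"))
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(world$legend, "zones_legend.csv")
  wcsv(world$tracks, "cyclone_tracks.csv")
  wcsv(world$floods, "flood_events.csv")
  wcsv(world$urban_fractions, "urban_fractions.csv")
  wcsv(world$hdi, "hdi_classes.csv")
  p <- world$precip
  M <- dim(p$values)[3]
  flat <- matrix(aperm(p$values, c(3, 2, 1)), nrow = p$spec$n_rows *
                   p$spec$n_cols, ncol = M, byrow = TRUE)
  grid <- expand.grid(col = seq_len(p$spec$n_cols),
                      row = seq_len(p$spec$n_rows))[, c(2, 1)]
  cube_df <- cbind(grid, as.data.frame(signif(flat, 10)))
  names(cube_df) <- c("row", "col", paste0("m", seq_len(M)))
  wcsv(cube_df, "precip_cube.csv")
  cal <- ((p$start_month - 1L + seq_len(M) - 1L) %% 12L) + 1L
  wcsv(data.frame(band = seq_len(M),
                  year = (p$start_month - 1L + seq_len(M) - 1L) %/% 12L + 1L,
                  month = cal),
       "precip_months.csv")
  meta <- list(n_rows = p$spec$n_rows, n_cols = p$spec$n_cols,
               cell_size = p$spec$cell_size,
               origin_lon = p$spec$origin_lon,
               origin_lat = p$spec$origin_lat,
               start_month = p$start_month)
  jsonlite::write_json(meta, file.path(dir, "precip_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(world$truth))
    jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a world's input files
#'
#' Inverse of [write_world()] (the `truth` sidecar is not reloaded).
#'
#' @param dir Directory holding the input files.
#' @return A world list (without `truth`).
#' @export
read_world <- function(dir) {
  rcsv <- function(f) utils::read.csv(file.path(dir, f))
  meta <- jsonlite::read_json(file.path(dir, "precip_meta.json"),
                              simplifyVector = TRUE)
  p_spec <- grid_spec(meta$n_rows, meta$n_cols, meta$cell_size,
                      meta$origin_lon, meta$origin_lat)
  cube_df <- rcsv("precip_cube.csv")
  M <- ncol(cube_df) - 2L
  cube <- array(0, c(p_spec$n_rows, p_spec$n_cols, M))
  for (i in seq_len(nrow(cube_df))) {
    cube[cube_df$row[i], cube_df$col[i], ] <-
      as.numeric(cube_df[i, 3:(M + 2L)])
  }
  list(population = read_raster(file.path(dir, "population.asc")),
       zones = read_raster(file.path(dir, "zones.asc")),
       legend = rcsv("zones_legend.csv"),
       agriculture = read_raster(file.path(dir, "agriculture.asc")),
       tracks = rcsv("cyclone_tracks.csv"),
       floods = rcsv("flood_events.csv"),
       precip = precip_cube(cube, p_spec, start_month = meta$start_month),
       urban_fractions = rcsv("urban_fractions.csv"),
       hdi = rcsv("hdi_classes.csv"))
}
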