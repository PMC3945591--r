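# Seeded synthetic-world generator. Emits every input the pipeline consumes:
# rectangular-block countries on a geographic grid, clustered integer
# populations (urban cores over a log-normal rural field), cyclone tracks,
# degree-snapped flood footprints, a seasonal monthly precipitation cube with
# injected deficit runs, an agriculture flag layer, tabulated urban fractions
# and development classes, plus a ground-truth sidecar.

#' Synthetic world configuration
#'
#' Defaults describe the stated world used throughout the test-suite: a
#' 36 x 36 one-degree tropical grid split into 9 rectangular countries,
#' populations of tens of thousands per cell with dense urban cores,
#' tens of cyclone and flood events over a two-decade record, and a
#' 240-month seasonal precipitation climatology with Poisson-injected
#' deficit runs.
#'
#' @param seed Integer RNG seed; same seed + config give a bit-identical
#'   world.
#' @param n_rows,n_cols,cell_size,origin_lon,origin_lat Grid geometry.
#' @param n_countries Number of rectangular countries.
#' @param cores_per_country Urban cores (dense cells) per country.
#' @param core_peak Population of a core cell before noise.
#' @param rural_meanlog,rural_sdlog Log-normal parameters of the rural
#'   population field (persons per cell, rounded to integers).
#' @param p_zero_pop Probability a cell is uninhabited.
#' @param n_cyclones Number of cyclone events (tracks).
#' @param cyclone_category_probs Sampling weights for categories 1-6.
#' @param n_floods Number of flood events.
#' @param max_flood_size Maximum footprint edge, whole degrees.
#' @param precip_coarse_factor Precipitation grid is this many times coarser
#'   than the population grid.
#' @param n_months Length of the monthly precipitation record (>= 36).
#' @param drought_lambda Mean number of injected deficit runs per coarse
#'   cell (Poisson).
#' @param deficit_factor Injected deficit months are scaled to this fraction
#'   of the seasonal baseline (must be <= 0.5 to qualify).
#' @param p_agriculture Probability a cell carries significant agriculture.
#' @param urban_fraction_range Range of per-country urban proportions.
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_rows = 36L, n_cols = 36L, cell_size = 1,
                         origin_lon = 0, origin_lat = 18,
                         n_countries = 9L,
                         cores_per_country = 2L,
                         core_peak = 5e5,
                         rural_meanlog = log(3e4), rural_sdlog = 1,
                         p_zero_pop = 0.05,
                         n_cyclones = 30L,
                         cyclone_category_probs = c(0.30, 0.25, 0.20,
                                                    0.12, 0.08, 0.05),
                         n_floods = 60L,
                         max_flood_size = 3L,
                         precip_coarse_factor = 3L,
                         n_months = 240L,
                         drought_lambda = 1.2,
                         deficit_factor = 0.3,
                         p_agriculture = 0.3,
                         urban_fraction_range = c(0.2, 0.8)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_months >= 36L, cfg$deficit_factor <= 0.5,
            cfg$p_agriculture >= 0, cfg$p_agriculture <= 1,
            all(cfg$urban_fraction_range >= 0),
            all(cfg$urban_fraction_range <= 1))
  class(cfg) <- "world_config"
  cfg
}

# Partition the grid into n rectangular blocks of near-equal size; returns an
# integer matrix of zone ids 1..n (every id present).
partition_countries <- function(n_rows, n_cols, n) {
  if (n > n_rows * n_cols) stop("more countries than grid cells")
  br <- max(1L, floor(sqrt(n)))
  bc <- ceiling(n / br)
  row_band <- pmin(ceiling(seq_len(n_rows) / (n_rows / br)), br)
  col_band <- pmin(ceiling(seq_len(n_cols) / (n_cols / bc)), bc)
  block <- outer(row_band, col_band, function(r, cc) (r - 1L) * bc + cc)
  pmin(block, n)   # fold unused trailing blocks into country n
}

#' Generate a synthetic world
#'
#' @param cfg A [world_config()].
#' @return A list with elements `population`, `zones`, `legend`,
#'   `agriculture` (rasters / data frame), `tracks`, `floods` (event data
#'   frames), `precip` (a [precip_cube()]), `urban_fractions`, `hdi`
#'   (tables) and `truth` (ground-truth sidecar: injected deficit runs and
#'   the per-country configuration actually drawn).
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(cfg$seed)
  spec <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size,
                    cfg$origin_lon, cfg$origin_lat)
  zone_m <- partition_countries(cfg$n_rows, cfg$n_cols, cfg$n_countries)
  ids <- seq_len(cfg$n_countries)
  legend <- data.frame(zone_id = ids,
                       iso3 = sprintf("S%02dX", ids),
                       name = sprintf("Synthland-%02d", ids))

  # population: rounded log-normal rural field, some uninhabited cells,
  # plus dense urban cores
  pop <- matrix(round(stats::rlnorm(cfg$n_rows * cfg$n_cols,
                                    cfg$rural_meanlog, cfg$rural_sdlog)),
                cfg$n_rows, cfg$n_cols)
  pop[stats::runif(length(pop)) < cfg$p_zero_pop] <- 0
  for (id in ids) {
    cells <- which(zone_m == id)
    k <- min(cfg$cores_per_country, length(cells))
    cores <- sample(cells, k)
    pop[cores] <- round(cfg$core_peak *
                          stats::runif(k, 0.8, 1.2)) + pop[cores]
  }
  # guarantee every country has at least one populated cell
  for (id in ids) {
    cells <- which(zone_m == id)
    if (all(pop[cells] == 0)) pop[cells[1]] <- 1000
  }

  agriculture <- matrix(as.numeric(
    stats::runif(cfg$n_rows * cfg$n_cols) < cfg$p_agriculture),
    cfg$n_rows, cfg$n_cols)

  # cyclone tracks: genesis weighted toward the southern (equatorward) half
  # of the grid, random heading, 5-12 points stepped about one cell apart
  lat_s <- cfg$origin_lat - cfg$n_rows * cfg$cell_size
  lon_e <- cfg$origin_lon + cfg$n_cols * cfg$cell_size
  tracks <- list()
  for (i in seq_len(cfg$n_cyclones)) {
    n_pts <- sample(5:12, 1)
    lat0 <- lat_s + (cfg$origin_lat - lat_s) * stats::rbeta(1, 2, 3)
    lon0 <- stats::runif(1, cfg$origin_lon, lon_e)
    heading <- stats::runif(1, 0, 2 * pi)
    step <- cfg$cell_size
    drift <- stats::rnorm(n_pts, 0, 0.3)
    lons <- lon0 + cumsum(c(0, rep(step * cos(heading), n_pts - 1))) +
      c(0, cumsum(drift[-1] * 0.2))
    lats <- lat0 + cumsum(c(0, rep(step * sin(heading), n_pts - 1)))
    tracks[[i]] <- data.frame(
      event_id = i, point_index = seq_len(n_pts), lon = lons, lat = lats,
      category = sample(1:6, 1, prob = cfg$cyclone_category_probs))
  }
  tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(event_id = integer(0), point_index = integer(0),
               lon = numeric(0), lat = numeric(0), category = integer(0))

  # flood events: degree-snapped boxes, sizes 1..max_flood_size degrees
  floods <- list()
  if (cfg$n_floods > 0) {
    w <- sample(seq_len(cfg$max_flood_size), cfg$n_floods, replace = TRUE)
    h <- sample(seq_len(cfg$max_flood_size), cfg$n_floods, replace = TRUE)
    x0 <- floor(stats::runif(cfg$n_floods, cfg$origin_lon, lon_e - w))
    y0 <- floor(stats::runif(cfg$n_floods, lat_s, cfg$origin_lat - h))
    floods <- data.frame(event_id = seq_len(cfg$n_floods),
                         lon_min = x0, lat_min = y0,
                         lon_max = x0 + w, lat_max = y0 + h)
  } else {
    floods <- data.frame(event_id = integer(0), lon_min = numeric(0),
                         lat_min = numeric(0), lon_max = numeric(0),
                         lat_max = numeric(0))
  }

  # precipitation cube on the coarse grid: seasonal sinusoid around a
  # cell-specific baseline with multiplicative gamma noise, then injected
  # deficit runs of 3-5 months scaled to deficit_factor x baseline
  cf <- cfg$precip_coarse_factor
  p_rows <- max(1L, cfg$n_rows %/% cf)
  p_cols <- max(1L, cfg$n_cols %/% cf)
  p_spec <- grid_spec(p_rows, p_cols, cfg$cell_size * cf,
                      cfg$origin_lon, cfg$origin_lat)
  M <- cfg$n_months
  months <- seq_len(M)
  cube <- array(0, c(p_rows, p_cols, M))
  injected <- list()
  for (r in seq_len(p_rows)) {
    for (cc in seq_len(p_cols)) {
      base <- stats::runif(1, 40, 150)
      phase <- stats::runif(1, 0, 12)
      seasonal <- base * (1 + 0.6 * sin(2 * pi * (months + phase) / 12))
      noise <- stats::rgamma(M, shape = 12, rate = 12)
      series <- seasonal * noise
      n_runs <- stats::rpois(1, cfg$drought_lambda)
      runs <- list()
      used <- rep(FALSE, M)
      if (n_runs > 0) {
        for (j in seq_len(n_runs)) {
          len <- sample(3:5, 1)
          start <- sample(seq_len(M - len + 1), 1)
          span <- start:(start + len - 1)
          # keep at least one clean month between injected runs
          guard <- max(1, start - 1):min(M, start + len)
          if (any(used[guard])) next
          series[span] <- cfg$deficit_factor * seasonal[span]
          used[span] <- TRUE
          runs[[length(runs) + 1L]] <- c(start = start, length = len)
        }
      }
      cube[r, cc, ] <- series
      if (length(runs))
        injected[[sprintf("r%d_c%d", r, cc)]] <- runs
    }
  }
  precip <- precip_cube(cube, p_spec, start_month = 1L)

  urban_fractions <- data.frame(
    country_id = ids,
    proportion_urban = round(stats::runif(cfg$n_countries,
                                          cfg$urban_fraction_range[1],
                                          cfg$urban_fraction_range[2]), 3))
  hdi <- data.frame(
    country_id = ids,
    hdi_class = sample(c("Low", "Medium", "High", "Very High"),
                       cfg$n_countries, replace = TRUE))

  list(population = hx_raster(pop, spec),
       zones = hx_raster(zone_m, spec),
       legend = legend,
       agriculture = hx_raster(agriculture, spec),
       tracks = tracks,
       floods = floods,
       precip = precip,
       urban_fractions = urban_fractions,
       hdi = hdi,
       truth = list(seed = cfg$seed, injected_drought_runs = injected,
                    n_cyclones = cfg$n_cyclones, n_floods = cfg$n_floods))
}

#' Extreme-country end-to-end fixture
#'
#' Builds a deterministic world in which country 1 monopolizes the top
#' decile of every hazard: its (few) populated cells carry the strictly
#' largest event count for cyclone, drought and flood, the middle countries
#' carry a spread of smaller counts, and the last country has no events at
#' all. Run through the full pipeline, country 1 therefore scores exactly
#' 1.0 per hazard and 3.0 multi-hazard, and the event-free country scores
#' 0 — the two theoretical anchors of the exposure score.
#'
#' @param spec Optional [grid_spec()]; default a 20 x 20 one-degree grid
#'   with its north-west corner at (0 E, 10 N).
#' @param n_countries Number of vertical-strip countries (>= 2).
#' @return A world list shaped like [generate_world()]'s output.
#' @export
make_extreme_country_fixture <- function(spec = NULL, n_countries = 4L) {
  if (n_countries < 2L) stop("need at least 2 countries")
  if (is.null(spec)) spec <- grid_spec(20, 20, 1, origin_lon = 0,
                                       origin_lat = 10)
  if (n_countries > spec$n_cols)
    stop("more countries than grid columns")
  strip <- pmin(ceiling(seq_len(spec$n_cols) /
                          (spec$n_cols / n_countries)), n_countries)
  zone_m <- matrix(strip, spec$n_rows, spec$n_cols, byrow = TRUE)
  ids <- seq_len(n_countries)

  # country 1: two dense cells only; middle countries fully populated;
  # last country populated but event-free
  pop <- matrix(0, spec$n_rows, spec$n_cols)
  pop[zone_m > 1] <- 1e6
  c1_cells <- which(zone_m == 1)[1:2]
  pop[c1_cells] <- 1e6

  # per-cell target event counts: country 1 cells get the strict maximum,
  # middle countries cycle 1..6, last country stays at zero
  top_count <- 8L
  counts <- matrix(0L, spec$n_rows, spec$n_cols)
  mid <- which(zone_m > 1 & zone_m < n_countries & pop > 0)
  if (length(mid)) counts[mid] <- rep_len(1:6, length(mid))
  counts[c1_cells] <- top_count

  lons <- cell_center_lons(spec)
  lats <- cell_center_lats(spec)
  cells <- which(counts > 0)
  rows <- ((cells - 1L) %% spec$n_rows) + 1L
  cols <- ((cells - 1L) %/% spec$n_rows) + 1L

  # floods: one single-cell degree box per event, repeated count times
  reps <- rep(seq_along(cells), counts[cells])
  floods <- data.frame(
    event_id = seq_along(reps),
    lon_min = floor(lons[cols[reps]] - 0.5),
    lat_min = floor(lats[rows[reps]] - 0.5),
    lon_max = floor(lons[cols[reps]] - 0.5) + 1,
    lat_max = floor(lats[rows[reps]] - 0.5) + 1)

  # cyclones: one single-point category-1 track per event at the cell
  # centre; the 50 km default buffer covers only that cell on a 1-deg grid
  tracks <- data.frame(
    event_id = seq_along(reps),
    point_index = 1L,
    lon = lons[cols[reps]],
    lat = lats[rows[reps]],
    category = 1L)

  # drought: flat 100 mm climatology; a cell with target count k receives k
  # three-month runs at 40 mm separated by one clean month (10-year cube,
  # so per-calendar-month medians stay at 100 mm)
  M <- 120L
  cube <- array(100, c(spec$n_rows, spec$n_cols, M))
  for (i in seq_along(cells)) {
    k <- counts[cells[i]]
    for (j in seq_len(k)) {
      span <- (4L * (j - 1L) + 1L):(4L * (j - 1L) + 3L)
      cube[rows[i], cols[i], span] <- 40
    }
  }
  precip <- precip_cube(cube, spec, start_month = 1L)

  list(population = hx_raster(pop, spec),
       zones = hx_raster(zone_m, spec),
       legend = data.frame(zone_id = ids, iso3 = sprintf("S%02dX", ids),
                           name = sprintf("Synthland-%02d", ids)),
       agriculture = hx_raster(matrix(0, spec$n_rows, spec$n_cols), spec),
       tracks = tracks,
       floods = floods,
       precip = precip,
       urban_fractions = data.frame(country_id = ids,
                                    proportion_urban = rep(0.3, n_countries)),
       hdi = data.frame(country_id = ids,
                        hdi_class = rep_len(c("Low", "Medium", "High",
                                              "Very High"), n_countries)),
       truth = list(extreme_country = 1L, zero_event_country = n_countries,
                    top_count = top_count, target_counts_cells = cells))
}
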