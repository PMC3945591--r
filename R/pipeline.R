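# End-to-end pipeline driver. Each stage reads ordinary files written by the
# stage before it and writes ordinary files, so any input dataset can be
# replaced and only the stages downstream of it re-run.

#' Pipeline configuration
#'
#' @param synthetic Generate inputs with [generate_world()] (`TRUE`) or use
#'   an existing input directory.
#' @param world A [world_config()] used when `synthetic` (its seed is
#'   overridden by `seed`).
#' @param input_dir Directory of input files (defaults to
#'   `<output_dir>/inputs`, where synthetic inputs are written).
#' @param output_dir Directory for stage outputs and reports.
#' @param seed Integer seed for the synthetic world.
#' @param radii_km Cyclone category buffer radii (km).
#' @param min_median_mm Drought eligibility floor (mm).
#' @param density_threshold Persons-per-km2 floor of the valid-cell mask.
#' @param log_level `"info"` to narrate stages, `"quiet"` to silence.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            world = world_config(),
                            input_dir = NULL,
                            output_dir = tempfile("hazex_run_"),
                            seed = 1L,
                            radii_km = default_cyclone_radii,
                            min_median_mm = 1,
                            density_threshold = 5,
                            log_level = "info") {
  cfg <- as.list(environment())
  if (is.null(cfg$input_dir)) cfg$input_dir <- file.path(output_dir, "inputs")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a JSON file
#'
#' Scalar keys mirror the arguments of [pipeline_config()]; a `world`
#' object holds [world_config()] overrides.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  wc_args <- raw$world
  raw$world <- NULL
  wc <- if (is.null(wc_args)) world_config() else
    do.call(world_config, wc_args)
  args <- raw[names(raw) %in% names(formals(pipeline_config))]
  args$world <- wc
  do.call(pipeline_config, args)
}

pipeline_stages <- c("simulate", "hazards", "classify", "exposure", "rank")

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[hazex] ", sprintf(...))
}

#' Run the exposure pipeline
#'
#' Stages, in order: `simulate` (synthetic inputs), `hazards` (event records
#' to frequency grids), `classify` (resample to the population grid, apply
#' the valid-cell mask, decile, weight; classify urban/rural), `exposure`
#' (cell and country exposure), `rank` (ranking, quintiles, development
#' class averages, report export). Identical configuration and seed produce
#' byte-identical report files.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Stages to run, a contiguous subset of
#'   `c("simulate", "hazards", "classify", "exposure", "rank")`. Stages not
#'   run must have their outputs already present.
#' @return Invisibly, a list with the output directory and the paths of the
#'   report files.
#' @export
run_pipeline <- function(cfg = pipeline_config(), stages = pipeline_stages) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    ok <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    invisible(ok)
  }

  run_stage("simulate", function() {
    if (!cfg$synthetic) {
      log_msg(cfg, "simulate: skipped (synthetic mode off)")
      return(NULL)
    }
    wc <- cfg$world
    wc$seed <- as.integer(cfg$seed)
    world <- generate_world(wc)
    write_world(world, cfg$input_dir)
    log_msg(cfg, "simulate: wrote inputs for %d countries on a %dx%d grid",
            nrow(world$legend), world$population$spec$n_rows,
            world$population$spec$n_cols)
  })

  hz_dir <- file.path(out, "hazards")
  run_stage("hazards", function() {
    world <- read_world(cfg$input_dir)
    dir.create(hz_dir, showWarnings = FALSE, recursive = TRUE)
    spec <- world$population$spec
    cyc <- cyclone_frequency(world$tracks, spec, cfg$radii_km)
    flo <- flood_frequency(world$floods, spec)
    dro <- drought_frequency(world$precip, cfg$min_median_mm)
    write_raster(cyc, file.path(hz_dir, "freq_cyclone.asc"))
    write_raster(flo, file.path(hz_dir, "freq_flood.asc"))
    write_raster(dro, file.path(hz_dir, "freq_drought.asc"))
    log_msg(cfg, "hazards: %d cyclone, %d flood events; %d drought cells hit",
            length(unique(world$tracks$event_id)), nrow(world$floods),
            sum(dro$values > 0))
  })

  cl_dir <- file.path(out, "classified")
  run_stage("classify", function() {
    world <- read_world(cfg$input_dir)
    dir.create(cl_dir, showWarnings = FALSE, recursive = TRUE)
    spec <- world$population$spec
    areas <- cell_areas(spec)
    mask <- valid_cell_mask(world$population, areas, world$agriculture,
                            cfg$density_threshold)
    for (hz in c("cyclone", "flood", "drought")) {
      freq <- read_raster(file.path(hz_dir, sprintf("freq_%s.asc", hz)))
      if (!spec_equal(freq$spec, spec))
        freq <- resample_nearest(freq, spec)
      dec <- to_deciles(freq, mask)
      write_raster(dec, file.path(cl_dir, sprintf("decile_%s.asc", hz)))
      write_raster(decile_weights(dec),
                   file.path(cl_dir, sprintf("weight_%s.asc", hz)))
    }
    ur <- classify_urban_rural(world$population, world$zones,
                               world$urban_fractions)
    write_raster(ur$mask, file.path(cl_dir, "urban_rural.asc"))
    utils::write.csv(ur$table, file.path(cl_dir, "urban_thresholds.csv"),
                     row.names = FALSE, quote = FALSE)
    log_msg(cfg, "classify: %d valid cells, %d urban cells",
            sum(mask), sum(ur$mask$values == 1, na.rm = TRUE))
  })

  ex_dir <- file.path(out, "exposure")
  run_stage("exposure", function() {
    world <- read_world(cfg$input_dir)
    dir.create(ex_dir, showWarnings = FALSE, recursive = TRUE)
    ur <- list(mask = read_raster(file.path(cl_dir, "urban_rural.asc")))
    exposures <- list()
    for (hz in c("cyclone", "drought", "flood")) {
      w <- read_raster(file.path(cl_dir, sprintf("weight_%s.asc", hz)))
      e <- cell_exposure(world$population, w)
      exposures[[hz]] <- e
      write_raster(e, file.path(ex_dir, sprintf("exposure_%s.asc", hz)))
    }
    write_raster(multi_hazard(exposures$cyclone, exposures$drought,
                              exposures$flood),
                 file.path(ex_dir, "exposure_multi.asc"))
    tab <- exposure_table(exposures, world$population, world$zones, ur)
    utils::write.csv(tab, file.path(ex_dir, "country_exposure.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    log_msg(cfg, "exposure: %d table rows over %d countries",
            nrow(tab), length(unique(tab$country_id)))
  })

  rep_dir <- file.path(out, "report")
  run_stage("rank", function() {
    world <- read_world(cfg$input_dir)
    tab <- utils::read.csv(file.path(ex_dir, "country_exposure.csv"))
    files <- export_report(tab, rep_dir)
    hdi_avg <- hdi_class_average(tab, world$hdi)
    utils::write.csv(hdi_avg, file.path(rep_dir, "hdi_averages.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    log_msg(cfg, "rank: wrote %d report files", length(files) + 1L)
  })

  report_files <- sort(list.files(rep_dir, full.names = TRUE))
  invisible(list(output_dir = out, report_files = report_files))
}
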