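# Population exposure: per-cell exposure = Pop_cell * H, aggregated per
# country as sum(exposure) / sum(population), optionally restricted to the
# urban or rural stratum, and averaged across development classes.

#' Per-cell population exposure
#'
#' Elementwise product of cell population and hazard weight H. Nodata in
#' either layer contributes 0 exposure.
#'
#' @param pop Population [hx_raster()].
#' @param H Hazard weight [hx_raster()] on the same grid (already resampled
#'   to the population grid).
#' @return An [hx_raster()] of exposure values (person-weighted likelihood).
#' @export
cell_exposure <- function(pop, H) {
  stop_if_spec_mismatch(pop$spec, H$spec, "pop and H")
  p <- pop$values; h <- H$values
  p[is.na(p)] <- 0; h[is.na(h)] <- 0
  hx_raster(p * h, pop$spec)
}

#' Multi-hazard cell exposure
#'
#' Sum of the three single-hazard exposure layers, equally weighted.
#'
#' @param cyc,dro,flo Single-hazard exposure [hx_raster()]s on one grid.
#' @return An [hx_raster()]; per-cell theoretical maximum is 3 x population.
#' @export
multi_hazard <- function(cyc, dro, flo) {
  stop_if_spec_mismatch(cyc$spec, dro$spec, "cyclone and drought exposure")
  stop_if_spec_mismatch(cyc$spec, flo$spec, "cyclone and flood exposure")
  z <- function(m) { m[is.na(m)] <- 0; m }
  hx_raster(z(cyc$values) + z(dro$values) + z(flo$values), cyc$spec)
}

#' Country-level average population exposure
#'
#' For each country, the sum of cell exposure over the selected cells
#' divided by the summed population of those cells. With no stratum the
#' score is the country-wide average (theoretical maximum 1.0 per hazard);
#' restricted to urban or rural cells both numerator and denominator use
#' only that stratum. A stratum with zero population yields a missing
#' score, not 0.
#'
#' @param e Exposure [hx_raster()] from [cell_exposure()]/[multi_hazard()].
#' @param pop Population [hx_raster()].
#' @param zones Country id [hx_raster()].
#' @param stratum Optional logical matrix (e.g. from [stratum_cells()])
#'   restricting both sums.
#' @return Data frame `country_id`, `score`, `population`.
#' @export
country_exposure <- function(e, pop, zones, stratum = NULL) {
  stop_if_spec_mismatch(e$spec, pop$spec, "exposure and pop")
  stop_if_spec_mismatch(e$spec, zones$spec, "exposure and zones")
  ev <- e$values; pv <- pop$values
  ev[is.na(ev)] <- 0; pv[is.na(pv)] <- 0
  if (!is.null(stratum)) {
    if (!identical(dim(stratum), dim(ev)))
      stop("stratum mask shape does not match the grid")
    ev[!stratum] <- 0
    pv[!stratum] <- 0
  }
  num <- zonal_sum(hx_raster(ev, e$spec), zones)
  den <- zonal_sum(hx_raster(pv, e$spec), zones)
  out <- merge(den, num, by = "zone_id", suffixes = c("_pop", "_exp"))
  score <- ifelse(out$sum_pop > 0, out$sum_exp / out$sum_pop, NA_real_)
  if (any(out$sum_pop == 0))
    warning("country with zero population in stratum: score reported missing")
  data.frame(country_id = out$zone_id, score = score,
             population = out$sum_pop)
}

#' Full country exposure table
#'
#' Builds the long-format table of exposure scores for every hazard
#' (cyclone, drought, flood and their equally-weighted multi-hazard sum)
#' crossed with every population stratum (total, urban, rural).
#'
#' @param exposures Named list of single-hazard exposure rasters, names
#'   `cyclone`, `drought`, `flood`.
#' @param pop Population [hx_raster()].
#' @param zones Country id [hx_raster()].
#' @param ur Result of [classify_urban_rural()], or `NULL` for total-only.
#' @return Data frame `country_id`, `hazard`, `stratum`, `score`,
#'   `population`.
#' @export
exposure_table <- function(exposures, pop, zones, ur = NULL) {
  stopifnot(all(c("cyclone", "drought", "flood") %in% names(exposures)))
  exposures <- exposures[c("cyclone", "drought", "flood")]
  exposures$multi <- multi_hazard(exposures$cyclone, exposures$drought,
                                  exposures$flood)
  strata <- if (is.null(ur)) "total" else c("total", "urban", "rural")
  rows <- list()
  for (hz in names(exposures)) {
    for (st in strata) {
      sel <- if (st == "total" && is.null(ur)) NULL else stratum_cells(ur, st)
      tab <- suppressWarnings(
        country_exposure(exposures[[hz]], pop, zones, stratum = sel))
      tab$hazard <- hz
      tab$stratum <- st
      rows[[paste(hz, st)]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$country_id, out$hazard, out$stratum),
      c("country_id", "hazard", "stratum", "score", "population")]
}

#' Average exposure by development class
#'
#' Person-weighted class averages: for each hazard and stratum, the pooled
#' sum of score x stratum population over the class's scored countries,
#' divided by the pooled stratum population. A `Global` row pools all
#' scored countries the same way. Countries without a class assignment are
#' excluded from class rows but still enter the Global row.
#'
#' @param table Country exposure table from [exposure_table()].
#' @param hdi Data frame `country_id`, `hdi_class` (one of `Low`, `Medium`,
#'   `High`, `Very High`).
#' @return Data frame `hdi_class`, `hazard`, `stratum`, `score`.
#' @export
hdi_class_average <- function(table, hdi) {
  classes <- c("Low", "Medium", "High", "Very High")
  if (!all(hdi$hdi_class %in% classes))
    stop("unknown HDI class: ",
         paste(setdiff(unique(hdi$hdi_class), classes), collapse = ", "))
  table$hdi_class <- hdi$hdi_class[match(table$country_id, hdi$country_id)]
  wavg <- function(d) {
    d <- d[!is.na(d$score) & d$population > 0, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    sum(d$score * d$population) / sum(d$population)
  }
  combos <- unique(table[, c("hazard", "stratum")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- table[table$hazard == combos$hazard[i] &
                 table$stratum == combos$stratum[i], , drop = FALSE]
    for (cl in c("Global", classes)) {
      d <- if (cl == "Global") sub else sub[!is.na(sub$hdi_class) &
                                            sub$hdi_class == cl, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        hdi_class = cl, hazard = combos$hazard[i],
        stratum = combos$stratum[i], score = wavg(d))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative difference from a reference score, in percent
#'
#' `100 * (value - reference) / reference`; missing when the reference is
#' not positive.
#'
#' @param value,reference Scores.
#' @return Percent difference (positive = above the reference).
#' @export
relative_difference <- function(value, reference) {
  ifelse(is.na(reference) | reference <= 0, NA_real_,
         100 * (value - reference) / reference)
}
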