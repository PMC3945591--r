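# Country-specific urban/rural classification. The tabulated national urban
# proportion is matched by selecting the most-populated cells of the country
# until their cumulative population is as close as possible to
# fraction * country population; the reported "threshold" is the smallest
# selected cell population.

#' Urban population threshold for one country
#'
#' Sorts a country's cell populations in descending order (ties broken by
#' original index, ascending) and selects the prefix whose cumulative
#' population best matches `fraction` times the country total. Cells with
#' zero population are never selected: uninhabited cells stay rural.
#'
#' @param cell_pops Non-negative per-cell populations of one country.
#' @param fraction Target urban proportion in `[0, 1]`.
#' @return A list: `threshold` (population of the smallest urban cell, `Inf`
#'   when no cell is selected), `selected` (integer indices into
#'   `cell_pops`), `achieved_share` (selected population over total), and
#'   `k` (number of selected cells).
#' @export
urban_threshold <- function(cell_pops, fraction) {
  if (any(cell_pops < 0)) stop("negative cell population")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  total <- sum(cell_pops)
  empty <- list(threshold = Inf, selected = integer(0),
                achieved_share = if (total > 0) 0 else NA_real_, k = 0L)
  pos <- which(cell_pops > 0)
  if (!length(pos)) {
    if (fraction > 0)
      warning("degenerate country: no populated cells, nothing urban")
    return(empty)
  }
  ord <- pos[order(-cell_pops[pos], pos)]
  cum <- c(0, cumsum(cell_pops[ord]))
  target <- fraction * total
  k <- which.min(abs(cum - target)) - 1L   # smallest k on ties
  list(threshold = if (k == 0L) Inf else cell_pops[ord[k]],
       selected = ord[seq_len(k)],
       achieved_share = cum[k + 1L] / total,
       k = k)
}

#' Classify every cell urban or rural
#'
#' Applies [urban_threshold()] independently per country: each country gets
#' its own population threshold so the same cell population can be urban in
#' one country and rural in another, following the country's own tabulated
#' urban proportion.
#'
#' @param pop Population [hx_raster()] (persons per cell).
#' @param zones Country [hx_raster()] of integer zone ids (`NA` = ocean).
#' @param fractions Data frame with columns `country_id` and
#'   `proportion_urban`; every country present in `zones` must appear.
#' @return A list: `mask` (an [hx_raster()], 1 = urban, 0 = rural, `NA`
#'   outside any country) and `table` (data frame `country_id`, `threshold`,
#'   `achieved_share`).
#' @export
classify_urban_rural <- function(pop, zones, fractions) {
  stop_if_spec_mismatch(pop$spec, zones$spec, "pop and zones")
  z <- zones$values
  p <- pop$values
  p[is.na(p)] <- 0
  ids <- sort(unique(as.integer(z[!is.na(z)])))
  missing_ids <- setdiff(ids, fractions$country_id)
  if (length(missing_ids))
    stop("no urban fraction for country: ",
         paste(missing_ids, collapse = ", "))
  lab <- matrix(NA_real_, nrow(z), ncol(z))
  lab[!is.na(z)] <- 0
  res <- data.frame(country_id = ids, threshold = NA_real_,
                    achieved_share = NA_real_)
  n_r <- nrow(z)
  n_c <- ncol(z)
  for (i in seq_along(ids)) {
    cells <- which(!is.na(z) & z == ids[i])
    # tie-break among equal-population cells follows row-major cell order
    rm_idx <- ((cells - 1L) %% n_r) * n_c + ((cells - 1L) %/% n_r) + 1L
    cells <- cells[order(rm_idx)]
    fr <- fractions$proportion_urban[match(ids[i], fractions$country_id)]
    ut <- urban_threshold(p[cells], fr)
    lab[cells[ut$selected]] <- 1
    res$threshold[i] <- ut$threshold
    res$achieved_share[i] <- ut$achieved_share
  }
  list(mask = hx_raster(lab, pop$spec), table = res)
}

#' Stratum selector from an urban/rural mask
#'
#' @param ur Result of [classify_urban_rural()].
#' @param stratum `"total"`, `"urban"` or `"rural"`.
#' @return Logical matrix selecting the stratum's cells.
#' @export
stratum_cells <- function(ur, stratum = c("total", "urban", "rural")) {
  stratum <- match.arg(stratum)
  m <- ur$mask$values
  switch(stratum,
         total = !is.na(m),
         urban = !is.na(m) & m == 1,
         rural = !is.na(m) & m == 0)
}
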