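# Independent brute-force oracles the vectorized implementation is checked
# against. These deliberately use naive per-cell loops and first-principles
# definitions, not the package's own code paths.

# per-cell loop zonal sum
oracle_zonal_sum <- function(values, zones) {
  v <- values$values; z <- zones$values
  out <- list()
  for (i in seq_along(v)) {
    if (is.na(z[i])) next
    key <- as.character(as.integer(z[i]))
    x <- if (is.na(v[i])) 0 else v[i]
    out[[key]] <- (out[[key]] %||% 0) + x
  }
  ids <- sort(as.integer(names(out)))
  data.frame(zone_id = ids, sum = vapply(as.character(ids),
                                         function(k) out[[k]], numeric(1)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent great-circle distance (spherical law of cosines)
oracle_gc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0 * acos(pmin(1, pmax(-1, d)))
}

# brute-force cyclone coverage: loops every cell x every track point
oracle_cyclone_freq <- function(tracks, spec, radii) {
  counts <- matrix(0, spec$n_rows, spec$n_cols)
  lons <- cell_center_lons(spec)
  lats <- cell_center_lats(spec)
  for (id in unique(tracks$event_id)) {
    ev <- tracks[tracks$event_id == id, ]
    radius <- radii[[as.character(ev$category[1])]]
    for (rr in seq_len(spec$n_rows)) for (cc in seq_len(spec$n_cols)) {
      hit <- FALSE
      for (k in seq_len(nrow(ev))) {
        if (oracle_gc_km(ev$lon[k], ev$lat[k], lons[cc], lats[rr]) <= radius)
          hit <- TRUE
      }
      if (hit) counts[rr, cc] <- counts[rr, cc] + 1
    }
  }
  counts
}

# exhaustive drought-run scan: enumerate every window start, find maximal
# qualifying runs by direct inspection
oracle_drought_events <- function(series, min_median_mm = 1,
                                  start_month = 1L) {
  cal <- ((start_month - 1L + seq_along(series) - 1L) %% 12L) + 1L
  med <- vapply(1:12, function(m) {
    x <- series[cal == m]
    if (length(x)) stats::median(x) else NA_real_
  }, numeric(1))[cal]
  q <- !is.na(med) & med >= min_median_mm & series <= 0.5 * med
  n_events <- 0
  i <- 1
  while (i <= length(q)) {
    if (q[i]) {
      j <- i
      while (j < length(q) && q[j + 1]) j <- j + 1
      if (j - i + 1 >= 3) n_events <- n_events + 1
      i <- j + 1
    } else i <- i + 1
  }
  n_events
}

# rank/quantile decile oracle: brute-force nearest-rank boundaries
oracle_deciles <- function(counts) {
  if (length(unique(counts)) == 1L) return(rep(10, length(counts)))
  srt <- sort(counts)
  n <- length(srt)
  bounds <- sapply(1:9, function(i) srt[ceiling(i * n / 10)])
  sapply(counts, function(x) 1 + sum(bounds < x))
}

# exhaustive prefix search for the urban threshold
oracle_urban_prefix <- function(pops, fraction) {
  pos <- which(pops > 0)
  ord <- pos[order(-pops[pos], pos)]
  target <- fraction * sum(pops)
  best_k <- 0L
  best <- abs(0 - target)
  cum <- 0
  for (k in seq_along(ord)) {
    cum <- cum + pops[ord[k]]
    if (abs(cum - target) < best - 1e-12) {
      best <- abs(cum - target)
      best_k <- k
    }
  }
  list(k = best_k, selected = ord[seq_len(best_k)])
}

# per-cell loop country score
oracle_country_score <- function(e, pop, zones, id, stratum = NULL) {
  num <- 0; den <- 0
  for (i in seq_along(pop$values)) {
    if (is.na(zones$values[i]) || zones$values[i] != id) next
    if (!is.null(stratum) && !stratum[i]) next
    p <- pop$values[i]; x <- e$values[i]
    if (is.na(p)) p <- 0
    if (is.na(x)) x <- 0
    num <- num + x
    den <- den + p
  }
  if (den == 0) NA_real_ else num / den
}

# small random world helper used by property suites
random_raster <- function(spec, rng = function(n) rpois(n, 3)) {
  hx_raster(matrix(rng(spec$n_rows * spec$n_cols),
                   spec$n_rows, spec$n_cols), spec)
}
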