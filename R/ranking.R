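# Country ranking with the competition ("minimum") tie convention and
# quintile display classes; CSV report export.

#' Rank countries by exposure score
#'
#' Descending competition ranking: a country's rank is one plus the number
#' of countries with a strictly greater score, so tied scores share a rank
#' and the group of zero-exposure countries always ranks at (number of
#' positive-score countries) + 1. Missing scores are excluded.
#'
#' @param scores Either a named numeric vector (names = country ids) or a
#'   data frame with columns `country_id` and `score`.
#' @return Data frame `country_id`, `score`, `rank`, sorted by rank then
#'   country id.
#' @export
rank_countries <- function(scores) {
  if (is.data.frame(scores)) {
    df <- data.frame(country_id = scores$country_id, score = scores$score)
  } else {
    df <- data.frame(country_id = names(scores), score = as.numeric(scores))
  }
  df <- df[!is.na(df$score), , drop = FALSE]
  if (!nrow(df))
    return(data.frame(country_id = df$country_id, score = numeric(0),
                      rank = integer(0)))
  df$rank <- vapply(df$score, function(s) 1L + sum(df$score > s), integer(1))
  df <- df[order(df$rank, df$country_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Quintile display classes
#'
#' Splits the ranked countries into five classes of (nearly) equal size by
#' rank order; class 1 holds the most-exposed fifth. Countries sharing a
#' rank always share a class: a tie group takes the class of its first
#' position.
#'
#' @param ranks Output of [rank_countries()].
#' @return The input with a `quintile` column added.
#' @export
quintile_classes <- function(ranks) {
  n <- nrow(ranks)
  if (n == 0L) { ranks$quintile <- integer(0); return(ranks) }
  if (n < 5L) {
    warning("fewer than 5 countries: all placed in quintile 1")
    ranks$quintile <- 1L
    return(ranks)
  }
  pos_class <- ceiling(seq_len(n) * 5 / n)
  # tie groups take the class at the group's first position; positions of a
  # tie group are contiguous because the table is sorted by rank
  first_pos <- match(ranks$rank, ranks$rank)
  ranks$quintile <- pos_class[first_pos]
  ranks
}

#' Export the exposure report
#'
#' Writes one CSV per hazard x stratum combination (ranked country lists
#' with quintile classes) plus a combined long-format CSV, all with
#' deterministic column order and row sort (rank, then country id), so
#' re-exporting unchanged inputs reproduces byte-identical files. Countries
#' with a missing score appear in the combined file with empty cells.
#'
#' @param exposure Country exposure table from [exposure_table()].
#' @param path Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(exposure, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  combos <- unique(exposure[, c("hazard", "stratum")])
  combos <- combos[order(combos$hazard, combos$stratum), , drop = FALSE]
  combined <- list()
  for (i in seq_len(nrow(combos))) {
    hz <- combos$hazard[i]; st <- combos$stratum[i]
    sub <- exposure[exposure$hazard == hz & exposure$stratum == st, ,
                    drop = FALSE]
    rk <- quintile_classes(rank_countries(sub))
    rk$population <- sub$population[match(rk$country_id, sub$country_id)]
    rk <- rk[, c("country_id", "score", "population", "rank", "quintile")]
    f <- file.path(path, sprintf("exposure_%s_%s.csv", hz, st))
    utils::write.csv(rk, f, row.names = FALSE, quote = FALSE, na = "")
    written <- c(written, f)
    all_rows <- sub[order(sub$country_id), , drop = FALSE]
    all_rows$rank <- rk$rank[match(all_rows$country_id, rk$country_id)]
    all_rows$quintile <- rk$quintile[match(all_rows$country_id, rk$country_id)]
    combined[[length(combined) + 1L]] <- all_rows
  }
  comb <- do.call(rbind, combined)
  comb <- comb[order(comb$hazard, comb$stratum, comb$country_id), ,
               drop = FALSE]
  f <- file.path(path, "exposure_combined.csv")
  utils::write.csv(comb, f, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(written, f))
}
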