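#' Assign breeding-ecology seasons to dates
#'
#' Seasons of equal four-month duration defined by the crows' breeding
#' ecology: breeding (February--May), parental care (June--September) and
#' nonbreeder (October--January).
#'
#' @param dates `Date` vector (or coercible).
#' @return character vector in
#'   `c("breeding", "parental_care", "nonbreeder")`.
#' @examples
#' assign_season(as.Date(c("2014-03-15", "2014-06-01", "2015-01-31")))
#' @export
assign_season <- function(dates) {
  mo <- as.POSIXlt(as.Date(dates))$mon + 1L
  out <- rep("nonbreeder", length(mo))
  out[mo %in% 2:5] <- "breeding"
  out[mo %in% 6:9] <- "parental_care"
  out
}

season_levels <- function() c("nonbreeder", "breeding", "parental_care")

#' Daily per-category proportions of unique individuals
#'
#' For every monitoring day, the proportion of unique identified marked
#' individuals seen that day that belongs to each presence category. Days
#' on which no categorised bird was seen carry `NA` proportions.
#'
#' @param records sightings data frame (see [simulate_transects()] for the
#'   schema); only identified marked birds contribute.
#' @param assignments data frame `bird_id`, `category` as returned by
#'   [assign_categories()].
#' @return data frame: `date`, `season`, `n_ids`, and one proportion
#'   column per category (`prop_resident`, ...), plus per-category unique
#'   counts (`n_resident`, ...).
#' @export
season_table <- function(records, assignments) {
  stopifnot(all(c("date", "bird_id", "marked") %in% names(records)))
  ids <- records[records$marked == 1L & !is.na(records$bird_id), ,
                 drop = FALSE]
  cat_of <- stats::setNames(assignments$category, assignments$bird_id)
  days <- sort(unique(as.Date(records$date)))
  out <- data.frame(date = days, season = assign_season(days),
                    n_ids = 0L, stringsAsFactors = FALSE)
  for (lev in category_levels()) {
    out[[paste0("n_", lev)]] <- 0L
    out[[paste0("prop_", lev)]] <- NA_real_
  }
  ids$date <- as.Date(ids$date)
  for (i in seq_along(days)) {
    seen <- unique(ids$bird_id[ids$date == days[i]])
    cats <- cat_of[seen]
    cats <- cats[!is.na(cats)]
    n <- length(cats)
    out$n_ids[i] <- n
    if (n > 0L) {
      tab <- table(factor(cats, levels = category_levels()))
      for (lev in category_levels()) {
        out[[paste0("n_", lev)]][i] <- as.integer(tab[[lev]])
        out[[paste0("prop_", lev)]][i] <- tab[[lev]] / n
      }
    }
  }
  out
}

#' Per-bird relative number of days seen, by season
#'
#' days seen / monitoring days, within each season, for every bird in
#' `assignments` (the block design behind the Monte-Carlo Friedman and
#' exact Wilcoxon comparisons).
#'
#' @param records sightings data frame.
#' @param assignments category assignments (`bird_id`, `category`).
#' @param monitoring_days `Date` vector of all days with transects.
#' @return data frame `bird_id`, `category`, one column per season with
#'   the relative number of days seen.
#' @export
relative_days_seen <- function(records, assignments, monitoring_days) {
  monitoring_days <- as.Date(monitoring_days)
  seas <- assign_season(monitoring_days)
  totals <- table(factor(seas, levels = season_levels()))
  ids <- records[records$marked == 1L & !is.na(records$bird_id), ,
                 drop = FALSE]
  ids$date <- as.Date(ids$date)
  out <- assignments[c("bird_id", "category")]
  for (s in season_levels()) out[[s]] <- 0
  for (i in seq_len(nrow(out))) {
    d <- unique(ids$date[ids$bird_id == out$bird_id[i]])
    ds <- assign_season(d)
    for (s in season_levels()) {
      tot <- as.integer(totals[[s]])
      out[[s]][i] <- if (tot > 0) sum(ds == s) / tot else NA_real_
    }
  }
  out
}
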