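#' Sighting-history features of a marked bird
#'
#' Computes the three clustering features from the days a bird was
#' identified: the number of days seen, the longest interior period
#' without observation, and the standard deviation of those periods.
#' Gaps are measured in monitoring days (days on which at least one
#' transect ran): absence is only observable when observers were present,
#' so calendar-day gaps would be inflated for every bird by observation
#' pauses. Leading and trailing censored intervals (before the first and
#' after the last sighting) are excluded from the gaps; an optional
#' `censored` flag includes them for sensitivity analyses.
#'
#' @param observation_days `Date` vector of days the bird was identified.
#' @param monitoring_days `Date` vector of all days with transects.
#' @param censored include the leading/trailing censored intervals as
#'   gaps (default FALSE).
#' @return list `days_seen`, `max_gap`, `gap_sd` (sample SD, 0 when fewer
#'   than 2 gaps).
#' @examples
#' mon <- as.Date("2014-01-01") + 0:24
#' extract_presence_features(mon[c(1, 5, 6, 20)], mon)
#' @export
extract_presence_features <- function(observation_days, monitoring_days,
                                      censored = FALSE) {
  observation_days <- sort(unique(as.Date(observation_days)))
  monitoring_days <- sort(unique(as.Date(monitoring_days)))
  if (length(observation_days) == 0L) stop("empty sighting history")
  idx <- match(observation_days, monitoring_days)
  if (anyNA(idx)) {
    stop("observation day outside the monitoring calendar: ",
         paste(format(observation_days[is.na(idx)]), collapse = ", "))
  }
  gaps <- diff(idx) - 1L
  if (censored) {
    gaps <- c(idx[1] - 1L, gaps, length(monitoring_days) - idx[length(idx)])
  }
  list(days_seen = length(idx),
       max_gap = if (length(gaps)) max(gaps) else 0L,
       gap_sd = if (length(gaps) >= 2L) stats::sd(gaps) else 0)
}

#' Feature matrix for all identified marked birds
#'
#' @param records sightings data frame.
#' @param monitoring_days `Date` vector of days with transects (defaults
#'   to the distinct record dates).
#' @param censored passed to [extract_presence_features()].
#' @return data frame `bird_id`, `days_seen`, `max_gap`, `gap_sd`.
#' @export
presence_features <- function(records, monitoring_days = NULL,
                              censored = FALSE) {
  ids <- records[records$marked == 1L & !is.na(records$bird_id), ,
                 drop = FALSE]
  if (nrow(ids) == 0L) stop("no identified marked birds in records")
  ids$date <- as.Date(ids$date)
  if (is.null(monitoring_days)) monitoring_days <- unique(as.Date(records$date))
  birds <- sort(unique(ids$bird_id))
  rows <- lapply(birds, function(b) {
    f <- extract_presence_features(ids$date[ids$bird_id == b],
                                   monitoring_days, censored)
    data.frame(bird_id = b, days_seen = f$days_seen, max_gap = f$max_gap,
               gap_sd = f$gap_sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardise a feature matrix to z-scores
#'
#' Columns are centred to mean 0 and scaled to sample SD 1. Constant
#' columns carry no clustering information and are dropped with a
#' warning.
#'
#' @param features numeric matrix or data frame (birds x features).
#' @return numeric matrix of z-scores (possibly fewer columns).
#' @export
standardize_features <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 birds to standardise")
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (ncol(m) == 0L) stop("all features constant")
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Complete-linkage clustering of standardised features
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) cut into `k` groups. Tie handling follows
#' [stats::hclust()]; ties have probability zero on continuous
#' standardised features.
#'
#' @param standardized numeric matrix from [standardize_features()].
#' @param k number of clusters.
#' @return integer cluster labels (length `nrow(standardized)`), with the
#'   `hclust` tree as attribute `tree`.
#' @export
hierarchical_cluster <- function(standardized, k = 3L) {
  n <- nrow(standardized)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of birds")
  hc <- stats::hclust(stats::dist(standardized, method = "euclidean"),
                      method = "complete")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Classify marked birds into presence categories
#'
#' Birds identified on fewer than `min_days` days are rare visitors a
#' priori. The remaining birds are clustered on their standardised
#' sighting-history features and the `k` clusters are mapped onto the
#' residency labels deterministically: descending mean days seen, ties
#' broken by ascending mean maximum gap -- resident (most days), then
#' continuous, then periodic.
#'
#' @param records sightings data frame.
#' @param monitoring_days days with transects (default: record dates).
#' @param min_days rare-visitor threshold (default 5).
#' @param k number of clusters among the eligible birds (default 3).
#' @param censored gap censoring flag, see [extract_presence_features()].
#' @return data frame of class `presence_categories`: `bird_id`,
#'   `days_seen`, `max_gap`, `gap_sd`, `category`, `cluster_id` (NA for
#'   rare visitors).
#' @export
assign_categories <- function(records, monitoring_days = NULL,
                              min_days = 5L, k = 3L, censored = FALSE) {
  feats <- presence_features(records, monitoring_days, censored)
  eligible <- feats$days_seen >= min_days
  if (sum(eligible) < k) {
    stop("fewer than k = ", k, " birds with >= ", min_days, " sighting days")
  }
  sub <- feats[eligible, , drop = FALSE]
  fm <- sub[c("days_seen", "max_gap", "gap_sd")]
  if (all(vapply(fm, function(col) length(unique(col)) == 1L, logical(1)))) {
    warning("all eligible birds have identical features; a single ",
            "effective cluster labelled 'resident' by the days-then-gap rule")
    labels <- rep(1L, nrow(sub))
  } else {
    z <- standardize_features(fm)
    labels <- hierarchical_cluster(z, k = k)
  }
  k_eff <- max(labels)
  # deterministic cluster -> label mapping
  stats_by <- data.frame(
    cluster = seq_len(k_eff),
    mean_days = vapply(seq_len(k_eff), function(cl)
      mean(sub$days_seen[labels == cl]), numeric(1)),
    mean_gap = vapply(seq_len(k_eff), function(cl)
      mean(sub$max_gap[labels == cl]), numeric(1)))
  ord <- order(-stats_by$mean_days, stats_by$mean_gap)
  lab_names <- c("resident", "continuous", "periodic")[seq_len(min(k_eff, 3L))]
  if (k_eff > 3L) lab_names <- c(lab_names, paste0("cluster", 4:k_eff))
  mapping <- stats::setNames(lab_names, stats_by$cluster[ord])
  if (length(unique(round(stats_by$mean_days, 9))) < k_eff) {
    warning("tied cluster profiles; label mapping used the documented ",
            "days-then-gap ordering")
  }
  feats$category <- "rare"
  feats$cluster_id <- NA_integer_
  feats$category[eligible] <- unname(mapping[as.character(labels)])
  feats$cluster_id[eligible] <- as.integer(labels)
  attr(feats, "tree") <- attr(labels, "tree")
  class(feats) <- c("presence_categories", class(feats))
  feats
}

#' @export
print.presence_categories <- function(x, ...) {
  cat("<presence_categories> ", nrow(x), " marked birds\n", sep = "")
  print(table(factor(x$category, levels = category_levels())))
  invisible(x)
}
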