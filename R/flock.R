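#' Resighting correction factor
#'
#' The within-day ratio of resightings among marked birds,
#' \deqn{CF = (CM_t - CM_{ind}) / CM_t,}
#' where \eqn{CM_t} is the total number of sightings of marked birds that
#' day (including resightings across transects) and \eqn{CM_{ind}} the
#' number of unique marked individuals. Used to deflate unmarked sighting
#' counts, which cannot be de-duplicated individually.
#'
#' @param CM_t total marked sightings (>= CM_ind).
#' @param CM_ind unique marked individuals.
#' @return CF in \[0, 1); `NA_real_` when `CM_t == 0` (undefined; callers
#'   substitute the study-period mean, see [daily_series()]).
#' @examples
#' compute_correction_factor(10, 8)  # 0.2
#' @export
compute_correction_factor <- function(CM_t, CM_ind) {
  stopifnot(length(CM_t) == length(CM_ind))
  if (any(CM_ind < 0 | CM_t < CM_ind)) {
    stop("need CM_t >= CM_ind >= 0")
  }
  ifelse(CM_t == 0, NA_real_, (CM_t - CM_ind) / CM_t)
}

#' Daily local flock size estimate
#'
#' The conservative minimum estimate of the number of crows using the
#' site on a day,
#' \deqn{FS_e = CM_{ind} + (CU - CU \cdot CF)/T,}
#' with \eqn{CU} the total unmarked sightings (including potential
#' resightings) and \eqn{T} the number of transects that day. The
#' division by sampling effort applies to the unmarked term only: unique
#' marked individuals are known exactly.
#'
#' @param CM_ind unique marked individuals seen that day.
#' @param CU total unmarked sightings that day.
#' @param CF correction factor in \[0, 1\].
#' @param T_n number of transects that day (>= 1).
#' @return numeric flock size estimate (not rounded).
#' @examples
#' estimate_daily_flock_size(8, 20, 0.2, 2)  # 16
#' @export
estimate_daily_flock_size <- function(CM_ind, CU, CF, T_n) {
  if (any(T_n < 1)) stop("T must be >= 1 (no transects that day)")
  if (any(CF < 0 | CF > 1)) stop("CF must lie in [0,1]")
  if (any(CM_ind < 0 | CU < 0)) stop("counts must be nonnegative")
  CM_ind + (CU - CU * CF) / T_n
}

#' Per-transect local flock size estimate
#'
#' The per-transect variant used as the response of the flock-size
#' models: unique marked individuals of the transect plus the transect's
#' unmarked sightings deflated by the day's correction factor. No
#' division by effort (a single transect).
#'
#' @param CM_ind_t unique marked individuals on the transect.
#' @param CU_t unmarked sightings on the transect.
#' @param CF_day the day's correction factor in \[0, 1\].
#' @return numeric estimate.
#' @examples
#' estimate_transect_flock_size(5, 10, 0.2)  # 13
#' @export
estimate_transect_flock_size <- function(CM_ind_t, CU_t, CF_day) {
  if (any(CF_day < 0 | CF_day > 1)) stop("CF must lie in [0,1]")
  CM_ind_t + CU_t * (1 - CF_day)
}

#' Daily flock-size series from raw sighting records
#'
#' Aggregates sightings into daily counts, computes the daily correction
#' factor and the daily and per-transect flock size estimates.
#'
#' Identified marked sightings contribute to \eqn{CM_t} (all sightings)
#' and \eqn{CM_{ind}} (unique birds). Unidentifiable marked birds
#' (`marked == 1`, missing `bird_id`) are real birds whose resighting
#' status is unknown; they are counted with the unmarked sightings
#' \eqn{CU} for abundance (they are excluded from identity-level analyses
#' only). Days with \eqn{CM_t = 0} have an undefined CF and receive the
#' study-period mean CF instead; exact duplicate rows for the same
#' identified bird in the same session are de-duplicated.
#'
#' @param records sightings data frame with at least `date`, `session`,
#'   `bird_id`, `marked`.
#' @return data frame of class `flock_series`: one row per observation
#'   day with `date`, `CM_t`, `CM_ind`, `CU`, `T`, `CF`, `CF_imputed`,
#'   `FS_e`; attribute `transects`: per-transect data frame (`date`,
#'   `session`, `CM_ind_t`, `CU_t`, `CF_day`, `FS_e_t`); attribute
#'   `n_unidentified`: count of unidentifiable marked sightings folded
#'   into CU.
#' @export
daily_series <- function(records) {
  stopifnot(all(c("date", "session", "bird_id", "marked") %in% names(records)))
  if (nrow(records) == 0L) stop("no records")
  records$date <- as.Date(records$date)
  idd <- records$marked == 1L & !is.na(records$bird_id)
  # de-duplicate only exact duplicate rows of identified birds (double
  # data entry); a bird genuinely seen twice in a session differs in
  # position/context and is a real resighting
  keep <- !idd | !duplicated(records)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " duplicate identified-bird records dropped")
  }
  records <- records[keep, , drop = FALSE]
  idd <- records$marked == 1L & !is.na(records$bird_id)
  n_unid <- sum(records$marked == 1L & is.na(records$bird_id))

  days <- sort(unique(records$date))
  agg <- lapply(days, function(d) {
    r <- records[records$date == d, , drop = FALSE]
    mk <- r[r$marked == 1L & !is.na(r$bird_id), , drop = FALSE]
    CM_t <- nrow(mk)
    CM_ind <- length(unique(mk$bird_id))
    CU <- sum(r$marked == 0L | is.na(r$bird_id))
    T_n <- length(unique(r$session))
    list(CM_t = CM_t, CM_ind = CM_ind, CU = CU, T_n = T_n, r = r)
  })
  CM_t <- vapply(agg, `[[`, numeric(1), "CM_t")
  CM_ind <- vapply(agg, `[[`, numeric(1), "CM_ind")
  CU <- vapply(agg, `[[`, numeric(1), "CU")
  T_n <- vapply(agg, `[[`, numeric(1), "T_n")
  CF <- compute_correction_factor(CM_t, CM_ind)
  imputed <- is.na(CF)
  if (all(imputed)) {
    CF[imputed] <- 0
    message("no marked sightings on any day; CF set to 0")
  } else if (any(imputed)) {
    CF[imputed] <- mean(CF, na.rm = TRUE)
    message(sum(imputed), " day(s) without marked sightings; ",
            "study-mean CF substituted")
  }
  FS_e <- estimate_daily_flock_size(CM_ind, CU, CF, T_n)
  out <- data.frame(date = days, CM_t = CM_t, CM_ind = CM_ind, CU = CU,
                    T = T_n, CF = CF, CF_imputed = imputed, FS_e = FS_e)
  # per-transect estimates with the day's CF
  tr <- do.call(rbind, lapply(seq_along(days), function(i) {
    r <- agg[[i]]$r
    ses <- sort(unique(r$session))
    do.call(rbind, lapply(ses, function(s) {
      rs <- r[r$session == s, , drop = FALSE]
      mk <- rs[rs$marked == 1L & !is.na(rs$bird_id), , drop = FALSE]
      CM_ind_t <- length(unique(mk$bird_id))
      CU_t <- sum(rs$marked == 0L | is.na(rs$bird_id))
      data.frame(date = days[i], session = s, CM_ind_t = CM_ind_t,
                 CU_t = CU_t, CF_day = CF[i],
                 FS_e_t = estimate_transect_flock_size(CM_ind_t, CU_t, CF[i]))
    }))
  }))
  attr(out, "transects") <- tr
  attr(out, "n_unidentified") <- n_unid
  class(out) <- c("flock_series", class(out))
  out
}

#' @export
print.flock_series <- function(x, ...) {
  cat("<flock_series> ", nrow(x), " observation days\n", sep = "")
  cat(sprintf("  mean CF %.3f (SD %.3f), mean FS_e %.1f (SD %.1f)\n",
              mean(x$CF), stats::sd(x$CF), mean(x$FS_e), stats::sd(x$FS_e)))
  if (any(x$CF_imputed)) {
    cat("  ", sum(x$CF_imputed), " day(s) with study-mean CF imputed\n", sep = "")
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more day(s)\n", sep = "")
  invisible(x)
}

#' Per-transect estimates of a flock series
#' @param series a `flock_series`.
#' @return the per-transect data frame stored alongside the daily series.
#' @export
transect_series <- function(series) {
  stopifnot(inherits(series, "flock_series"))
  attr(series, "transects")
}
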