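sightings_schema <- function() {
  c("date", "session", "bird_id", "marked", "age_class", "flying",
    "x_m", "y_m", "zone_id", "forested", "on_building", "food")
}

#' Read a sightings CSV
#'
#' Validates the column schema, parses dates and normalises the
#' `"unmarked"` identity token to a missing `bird_id`.
#'
#' @param path CSV path.
#' @return sightings data frame.
#' @export
read_sightings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sightings_schema(), names(df))
  if (length(missing_cols)) {
    stop("sightings file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  d <- as.Date(substr(as.character(df$date), 1L, 10L), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date at line(s) ",
         paste(utils::head(which(is.na(d)) + 1L, 5), collapse = ", "),
         " of ", path)
  }
  df$date <- d
  df$bird_id[df$bird_id %in% c("unmarked", "")] <- NA_character_
  df$marked <- as.integer(df$marked)
  df$flying <- as.integer(df$flying)
  if (anyNA(df$marked) || !all(df$marked %in% 0:1)) {
    stop("marked must be 0/1 in ", path)
  }
  df
}

#' Write a sightings CSV
#'
#' Missing identities are serialised as the `"unmarked"` token.
#' @param records sightings data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(records, path) {
  out <- records
  out$bird_id[is.na(out$bird_id)] <- "unmarked"
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read session covariates CSV
#' @param path CSV path.
#' @return data frame `date`, `session`, `weather`, `temperature`,
#'   `visitors`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "session", "weather", "temperature", "visitors")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("covariates file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  dup <- duplicated(df[c("date", "session")])
  if (any(dup)) stop("duplicate session covariate rows in ", path)
  df
}
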