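#' World configuration for the sighting simulator
#'
#' Describes the study site as a set of rectangular habitat zones with
#' ecological attributes, sight-blocking barrier segments, the study
#' calendar, and the transect schedule. Zone attributes mirror the habitat
#' descriptors used in the downstream subgroup models: openness
#' (`in_forest` / `out_of_forest`), man-made structure (`on_building` /
#' `off_building`) and the dominant food type of the zone.
#'
#' @param study_start,study_end `Date` (or coercible) study window bounds.
#' @param zones data frame with columns `zone_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`, `forested` (`"in_forest"`/`"out_of_forest"`), `on_building`
#'   (`"on_building"`/`"off_building"`) and `food` (one of
#'   `r paste0('"', food_levels(), '"', collapse = ", ")`). When zones
#'   overlap, the first-listed zone takes precedence.
#' @param barriers data frame with columns `x1,y1,x2,y2` (metres); may have
#'   zero rows.
#' @param summer_sessions logical; when TRUE, days in May--September run
#'   three transects (Morning, Noon, Afternoon) and the rest of the year
#'   two (Morning, Afternoon), emulating a daylight-driven schedule.
#' @return An object of class `world_config`.
#' @export
world_config <- function(study_start = as.Date("2014-01-08"),
                         study_end = as.Date("2015-01-31"),
                         zones = default_zones(),
                         barriers = default_barriers(),
                         summer_sessions = TRUE) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(is.data.frame(zones), nrow(zones) >= 1L,
            study_end > study_start)
  req <- c("zone_id", "xmin", "xmax", "ymin", "ymax",
           "forested", "on_building", "food")
  missing_cols <- setdiff(req, names(zones))
  if (length(missing_cols)) {
    stop("zones is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  coords <- unlist(zones[c("xmin", "xmax", "ymin", "ymax")])
  if (!all(is.finite(coords))) stop("zone coordinates must be finite")
  if (any(zones$xmax <= zones$xmin) || any(zones$ymax <= zones$ymin)) {
    stop("degenerate zone rectangle")
  }
  if (!all(zones$food %in% food_levels())) {
    stop("unknown food level; valid: ", paste(food_levels(), collapse = ", "))
  }
  if (is.null(barriers)) barriers <- empty_barriers()
  if (nrow(barriers) && !all(is.finite(unlist(barriers[c("x1","y1","x2","y2")])))) {
    stop("barrier coordinates must be finite")
  }
  structure(list(study_start = study_start, study_end = study_end,
                 zones = zones, barriers = barriers,
                 summer_sessions = isTRUE(summer_sessions)),
            class = "world_config")
}

food_levels <- function() {
  c("grass", "vegetarian", "mixed", "mainly_meat", "human_gastronomy")
}

session_levels <- function() c("Morning", "Noon", "Afternoon")

empty_barriers <- function() {
  data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
}

#' Default zoo-like zone layout (synthetic)
#'
#' Six rectangular zones tiling a 300 x 200 m site: a forested strip, open
#' lawns, animal enclosures with different food regimes and a gastronomy
#' area. Entirely synthetic; loosely shaped like an urban zoo.
#' @return data frame of zones.
#' @export
default_zones <- function() {
  data.frame(
    zone_id    = c("forest", "lawn", "carnivores",
                   "gastronomy", "herbivores", "mixed_enclosures"),
    xmin       = c(0,   100, 200, 0,   100, 200),
    xmax       = c(100, 200, 300, 100, 200, 300),
    ymin       = c(0,   0,   0,   100, 100, 100),
    ymax       = c(100, 100, 100, 200, 200, 200),
    forested   = c("in_forest", rep("out_of_forest", 5)),
    on_building = c("off_building", "off_building", "off_building",
                    "off_building", "off_building", "on_building"),
    food       = c("grass", "grass", "mainly_meat",
                   "human_gastronomy", "vegetarian", "mixed"),
    stringsAsFactors = FALSE
  )
}

#' Default barrier set (synthetic)
#'
#' A few wall/hedge segments inside the enclosure zones so that the
#' line-of-sight rule is exercised by default.
#' @return data frame of segments.
#' @export
default_barriers <- function() {
  data.frame(
    x1 = c(150, 250, 60),
    y1 = c(120, 20, 40),
    x2 = c(150, 250, 60),
    y2 = c(180, 80, 120)
  )
}

#' Materialise a world from its configuration
#'
#' Deterministic for a fixed seed. Precomputes the transect schedule
#' (monitoring days and session labels) and zone lookup structures used by
#' the transect simulator. Monitoring runs two to three days a week
#' (Tuesday and Friday every week, Sunday on even weeks).
#'
#' @param config a [world_config()].
#' @param seed integer seed (reserved for stochastic site features; the
#'   default world is deterministic).
#' @return An object of class `crow_world` with elements `zones`,
#'   `barriers`, `calendar` (all study dates), `monitoring_days`, and
#'   `sessions` (data frame date x session label).
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  calendar <- seq(config$study_start, config$study_end, by = "day")
  wd <- as.POSIXlt(calendar)$wday            # 0 = Sunday
  wk <- as.integer(strftime(calendar, "%V"))
  monitor <- wd == 2L | wd == 5L | (wd == 0L & wk %% 2L == 0L)
  monitoring_days <- calendar[monitor]
  sessions <- do.call(rbind, lapply(seq_along(monitoring_days), function(i) {
    d <- monitoring_days[i]
    mo <- as.POSIXlt(d)$mon + 1L
    labs <- if (config$summer_sessions && mo %in% 5:9) {
      session_levels()
    } else {
      c("Morning", "Afternoon")
    }
    data.frame(date = rep(d, length(labs)), session = labs,
               stringsAsFactors = FALSE)
  }))
  # overlapping zones: first-listed wins; report once
  ov <- zones_overlap(config$zones)
  if (ov) message("overlapping zones detected; first-listed zone takes precedence")
  structure(list(zones = config$zones, barriers = config$barriers,
                 calendar = calendar, monitoring_days = monitoring_days,
                 sessions = sessions, config = config, seed = as.integer(seed)),
            class = "crow_world")
}

zones_overlap <- function(z) {
  n <- nrow(z)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (z$xmin[i] < z$xmax[j] && z$xmin[j] < z$xmax[i] &&
        z$ymin[i] < z$ymax[j] && z$ymin[j] < z$ymax[i]) return(TRUE)
  }
  FALSE
}

#' Map planar points to zones (first-listed precedence)
#' @param x,y numeric vectors (metres).
#' @param world a `crow_world`.
#' @return character vector of zone ids (NA outside every zone).
#' @keywords internal
locate_zone <- function(x, y, world) {
  z <- world$zones
  out <- rep(NA_character_, length(x))
  for (i in rev(seq_len(nrow(z)))) {
    inz <- x >= z$xmin[i] & x <= z$xmax[i] & y >= z$ymin[i] & y <= z$ymax[i]
    out[inz] <- z$zone_id[i]
  }
  out
}

#' @export
print.crow_world <- function(x, ...) {
  cat("<crow_world> ", format(x$config$study_start), " to ",
      format(x$config$study_end), "\n", sep = "")
  cat("  zones: ", nrow(x$zones), ", barriers: ", nrow(x$barriers), "\n", sep = "")
  cat("  monitoring days: ", length(x$monitoring_days),
      ", transect sessions: ", nrow(x$sessions), "\n", sep = "")
  invisible(x)
}
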