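#' Simulate session covariates
#'
#' Weather, temperature band and visitor pressure per transect session,
#' drawn independently per day with season-dependent distributions (all
#' sessions of a day share the day's weather and temperature; visitor
#' level is drawn per session). The covariates are exogenous: they do not
#' feed back on presence unless log-linear effects are configured in the
#' [agent_config()].
#'
#' @param sessions data frame `date`, `session` (from a `crow_world`).
#' @param seed integer seed.
#' @param weather_probs,temperature_probs named list per season of
#'   probability vectors over the factor levels.
#' @param visitor_probs probability vector over `few/some/many`.
#' @return data frame `date`, `session`, `weather`, `temperature`,
#'   `visitors`.
#' @export
simulate_covariates <- function(sessions, seed = 1L,
    weather_probs = list(
      breeding      = c(rain = 0.30, clouds = 0.40, sun = 0.30),
      parental_care = c(rain = 0.20, clouds = 0.35, sun = 0.45),
      nonbreeder    = c(rain = 0.30, clouds = 0.45, sun = 0.25)),
    temperature_probs = list(
      breeding      = c(cold = 0.45, warm = 0.50, hot = 0.05),
      parental_care = c(cold = 0.05, warm = 0.55, hot = 0.40),
      nonbreeder    = c(cold = 0.80, warm = 0.20, hot = 0.00)),
    visitor_probs = c(few = 0.30, some = 0.50, many = 0.20)) {
  set.seed(as.integer(seed))
  days <- unique(sessions$date)
  seas <- assign_season(days)
  wx <- character(length(days)); tp <- character(length(days))
  for (i in seq_along(days)) {
    wx[i] <- sample(names(weather_probs[[seas[i]]]), 1,
                    prob = weather_probs[[seas[i]]])
    tp[i] <- sample(names(temperature_probs[[seas[i]]]), 1,
                    prob = temperature_probs[[seas[i]]])
  }
  idx <- match(sessions$date, days)
  data.frame(date = sessions$date, session = sessions$session,
             weather = wx[idx], temperature = tp[idx],
             visitors = sample(names(visitor_probs), nrow(sessions),
                               replace = TRUE, prob = visitor_probs),
             stringsAsFactors = FALSE)
}

weather_levels <- function() c("rain", "clouds", "sun")
temperature_levels <- function() c("cold", "warm", "hot")
visitor_levels <- function() c("few", "some", "many")

#' Simulate transect sighting records
#'
#' For every transect session, each bird present that day is detected with
#' probability `detection` (independently per session, identically for
#' marked and unmarked birds -- the estimator's core assumption). Detected
#' birds are assigned to a zone and either join a shared foraging point
#' (with the age- and zone-dependent grouping propensity; group members are
#' scattered within `group_radius` metres of the point, guaranteeing
#' detectable subgroups under the 5 m chain rule) or forage solo at a
#' uniform position in the zone. A fraction of detected birds is recorded
#' in flight. Marked birds fail identification with probability
#' `id_failure` (ring lost / poor view), yielding `marked = 1` records with
#' missing `bird_id`.
#'
#' Session covariates may shift presence and grouping through the
#' log-linear `covariate_effects` of the [agent_config()]: for presence the
#' day's detection-eligibility is thinned by `exp(effect)` (capped at 1),
#' and for grouping the propensity odds are scaled by `exp(effect)`.
#'
#' @param world a `crow_world` from [generate_world()].
#' @param presence presence matrix from [simulate_presence()].
#' @param covariates covariates from [simulate_covariates()].
#' @param detection per-session detection probability in (0, 1].
#' @param agents the [agent_config()] (for grouping and effects).
#' @param grouping named propensities `c(juvenile=, nonjuvenile=)`.
#' @param food_group_bonus named multiplier of grouping odds per food
#'   level (widely scattered vegetarian food supports larger groups).
#' @param points_per_zone number of active foraging points per zone and
#'   session.
#' @param group_radius scatter radius around a foraging point (metres).
#' @param flying_prob probability a detected bird is recorded in flight.
#' @param id_failure probability an observed marked bird cannot be
#'   identified.
#' @param seed integer seed.
#' @return list with `records` (the sightings data frame: `date`,
#'   `session`, `bird_id`, `marked`, `age_class`, `flying`, `x_m`, `y_m`,
#'   `zone_id`, `forested`, `on_building`, `food`, `weather`,
#'   `temperature`, `visitors`), `truth` (data frame `date`,
#'   `true_flock_size`: distinct birds present per monitoring day) and
#'   `birds` (agent metadata).
#' @export
simulate_transects <- function(world, presence, covariates,
                               detection = 0.5,
                               agents = NULL,
                               grouping = c(juvenile = 0.8, nonjuvenile = 0.55),
                               food_group_bonus = c(grass = 1, vegetarian = 1.8,
                                                    mixed = 1, mainly_meat = 0.8,
                                                    human_gastronomy = 0.7),
                               points_per_zone = 2L,
                               group_radius = 2.5,
                               flying_prob = 0.10,
                               id_failure = 0.138,
                               seed = 1L) {
  stopifnot(inherits(world, "crow_world"))
  if (!(detection > 0 && detection <= 1)) stop("detection must be in (0,1]")
  sess <- world$sessions
  key <- paste(covariates$date, covariates$session)
  if (!all(paste(sess$date, sess$session) %in% key)) {
    stop("covariates must cover every transect session")
  }
  set.seed(as.integer(seed))
  birds <- attr(presence, "birds")
  zones <- world$zones
  eff <- if (!is.null(agents)) agents$covariate_effects else list()

  cov_effect <- function(covrow, what) {
    tot <- 0
    e <- eff[[what]]
    if (is.null(e)) return(0)
    for (fac in names(e)) {
      lev <- covrow[[fac]]
      if (!is.null(lev) && lev %in% names(e[[fac]])) tot <- tot + e[[fac]][[lev]]
    }
    tot
  }

  day_str <- colnames(presence)
  rec <- vector("list", nrow(sess))
  for (si in seq_len(nrow(sess))) {
    d <- sess$date[si]
    lab <- sess$session[si]
    ci <- which(covariates$date == d & covariates$session == lab)[1]
    covrow <- covariates[ci, ]
    di <- match(format(d), day_str)
    present <- which(presence[, di])
    if (!length(present)) { rec[[si]] <- NULL; next }
    # presence thinning by covariates (log-linear on detection eligibility)
    pe <- exp(cov_effect(covrow, "presence"))
    p_det <- min(1, detection * pe)
    det <- present[stats::runif(length(present)) < p_det]
    n <- length(det)
    if (!n) { rec[[si]] <- NULL; next }
    age <- birds$age_class[det]
    # zone choice: uniform over zones, weighted by area
    area <- (zones$xmax - zones$xmin) * (zones$ymax - zones$ymin)
    zi <- sample.int(nrow(zones), n, replace = TRUE, prob = area)
    # grouping decision
    g0 <- unname(grouping[age])
    bonus <- unname(food_group_bonus[zones$food[zi]])
    ge <- exp(cov_effect(covrow, "grouping"))
    odds <- g0 / (1 - g0) * bonus * ge
    pg <- odds / (1 + odds)
    grouped <- stats::runif(n) < pg
    flying <- stats::runif(n) < flying_prob
    grouped[flying] <- FALSE
    x <- numeric(n); y <- numeric(n)
    # foraging points per zone for this session
    px <- matrix(stats::runif(nrow(zones) * points_per_zone), nrow(zones))
    py <- matrix(stats::runif(nrow(zones) * points_per_zone), nrow(zones))
    pt <- sample.int(points_per_zone, n, replace = TRUE)
    for (k in seq_len(n)) {
      z <- zi[k]
      if (grouped[k]) {
        cx <- zones$xmin[z] + px[z, pt[k]] * (zones$xmax[z] - zones$xmin[z])
        cy <- zones$ymin[z] + py[z, pt[k]] * (zones$ymax[z] - zones$ymin[z])
        r <- group_radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        x[k] <- min(max(cx + r * cos(th), zones$xmin[z]), zones$xmax[z])
        y[k] <- min(max(cy + r * sin(th), zones$ymin[z]), zones$ymax[z])
      } else {
        x[k] <- stats::runif(1, zones$xmin[z], zones$xmax[z])
        y[k] <- stats::runif(1, zones$ymin[z], zones$ymax[z])
      }
    }
    id <- birds$bird_id[det]
    marked <- birds$marked[det]
    unid <- marked == 1L & stats::runif(n) < id_failure
    id[marked == 0L | unid] <- NA_character_
    rec[[si]] <- data.frame(
      date = rep(d, n), session = lab, bird_id = id, marked = marked,
      age_class = age, flying = as.integer(flying),
      x_m = x, y_m = y, zone_id = zones$zone_id[zi],
      forested = zones$forested[zi], on_building = zones$on_building[zi],
      food = zones$food[zi],
      weather = covrow$weather, temperature = covrow$temperature,
      visitors = covrow$visitors,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  if (is.null(records)) records <- empty_records()
  mon <- world$monitoring_days
  truth <- data.frame(
    date = mon,
    true_flock_size = vapply(mon, function(d) {
      di <- match(format(d), day_str)
      sum(presence[, di])
    }, integer(1)))
  list(records = records, truth = truth, birds = birds)
}

empty_records <- function() {
  data.frame(date = as.Date(character()), session = character(),
             bird_id = character(), marked = integer(),
             age_class = character(), flying = integer(),
             x_m = numeric(), y_m = numeric(), zone_id = character(),
             forested = character(), on_building = character(),
             food = character(), weather = character(),
             temperature = character(), visitors = character(),
             stringsAsFactors = FALSE)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [generate_world()], [simulate_presence()],
#' [simulate_covariates()] and [simulate_transects()] with per-stage seeds
#' derived from one top-level seed (seed, seed+1, seed+2, seed+3).
#'
#' @param world_cfg a [world_config()].
#' @param agents an [agent_config()].
#' @param detection per-session detection probability.
#' @param seed top-level integer seed.
#' @param ... passed to [simulate_transects()].
#' @return list `world`, `records`, `sessions` (covariates), `truth`,
#'   `birds`, `presence`.
#' @export
simulate_sightings <- function(world_cfg = world_config(),
                               agents = agent_config(),
                               detection = 0.5, seed = 1L, ...) {
  seed <- as.integer(seed)
  world <- generate_world(world_cfg, seed)
  presence <- simulate_presence(agents, world$calendar, seed + 1L)
  covariates <- simulate_covariates(world$sessions, seed + 2L)
  sim <- simulate_transects(world, presence, covariates,
                            detection = detection, agents = agents,
                            seed = seed + 3L, ...)
  list(world = world, records = sim$records, sessions = covariates,
       truth = sim$truth, birds = sim$birds, presence = presence)
}
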