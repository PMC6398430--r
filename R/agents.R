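#' Agent (bird population) configuration
#'
#' Defines a partially marked crow population with four residency
#' archetypes whose daily presence follows simple stochastic processes:
#' \describe{
#'   \item{resident}{daily Bernoulli presence with high probability;}
#'   \item{continuous}{daily Bernoulli presence with moderate-to-low
#'     probability (regular but not constant visitors);}
#'   \item{periodic}{alternating on/off blocks with geometric lengths;
#'     Bernoulli presence only inside on-blocks;}
#'   \item{rare}{a small number of visit days spread uniformly over the
#'     study period, with a site-fidelity probability governing whether a
#'     marked bird ever returns to the site at all (emulating ringed birds
#'     that left the area).}
#' }
#' Seasonal multipliers scale the daily presence probabilities per
#' archetype and season, producing the seasonal shifts in category
#' proportions the seasonal test battery targets.
#'
#' @param n_marked,n_unmarked population sizes.
#' @param archetype_mix named numeric proportions over
#'   `c("resident","continuous","periodic","rare")`, summing to 1; used for
#'   marked birds.
#' @param unmarked_mix archetype proportions for unmarked birds (defaults
#'   to a more site-faithful mix: unringed local birds).
#' @param p_resident,p_continuous daily presence probabilities.
#' @param periodic_on_mean,periodic_off_mean mean on/off block lengths in
#'   days.
#' @param periodic_block_size dispersion of block lengths (negative
#'   binomial size): 1 recovers geometric block lengths, larger values
#'   give more regular periodicity.
#' @param p_periodic_on daily presence probability inside an on-block.
#' @param rare_mean_days expected visit days of a returning rare bird.
#' @param rare_site_fidelity probability that a rare bird visits at all.
#' @param age_juvenile_prop proportion of juveniles.
#' @param seasonal_modifiers named list per archetype of named numeric
#'   multipliers per season (`breeding`, `parental_care`, `nonbreeder`);
#'   missing entries default to 1.
#' @param covariate_effects log-linear effects of session covariates on
#'   detection-eligible presence and on grouping odds, applied at
#'   simulation time by [simulate_transects()]; a list with optional
#'   elements `presence` and `grouping`, each a named list per factor of
#'   named level effects, e.g.
#'   `list(presence = list(weather = c(rain = -0.3)))`. Defaults to no
#'   effect.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(n_marked = 322L,
                         n_unmarked = 180L,
                         archetype_mix = c(resident = 0.08, continuous = 0.13,
                                           periodic = 0.05, rare = 0.74),
                         unmarked_mix = c(resident = 0.25, continuous = 0.35,
                                          periodic = 0.10, rare = 0.30),
                         p_resident = 0.75,
                         p_continuous = 0.15,
                         periodic_on_mean = 21,
                         periodic_off_mean = 45,
                         periodic_block_size = 1,
                         p_periodic_on = 0.5,
                         rare_mean_days = 2,
                         rare_site_fidelity = 0.25,
                         age_juvenile_prop = 0.10,
                         seasonal_modifiers = list(
                           resident   = c(breeding = 0.70),
                           continuous = c(parental_care = 1.8),
                           periodic   = c(breeding = 1.6)
                         ),
                         covariate_effects = list()) {
  chk_mix <- function(m, nm) {
    if (!setequal(names(m), archetype_levels())) {
      stop(nm, " must be named over ", paste(archetype_levels(), collapse = ", "))
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop(nm, " proportions must be nonnegative and sum to 1")
    }
    m[archetype_levels()]
  }
  archetype_mix <- chk_mix(archetype_mix, "archetype_mix")
  unmarked_mix <- chk_mix(unmarked_mix, "unmarked_mix")
  probs <- c(p_resident, p_continuous, p_periodic_on,
             rare_site_fidelity, age_juvenile_prop)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  stopifnot(n_marked >= 0, n_unmarked >= 0,
            periodic_on_mean > 0, periodic_off_mean > 0, rare_mean_days >= 0)
  structure(list(n_marked = as.integer(n_marked),
                 n_unmarked = as.integer(n_unmarked),
                 archetype_mix = archetype_mix, unmarked_mix = unmarked_mix,
                 p_resident = p_resident, p_continuous = p_continuous,
                 periodic_on_mean = periodic_on_mean,
                 periodic_off_mean = periodic_off_mean,
                 periodic_block_size = periodic_block_size,
                 p_periodic_on = p_periodic_on,
                 rare_mean_days = rare_mean_days,
                 rare_site_fidelity = rare_site_fidelity,
                 age_juvenile_prop = age_juvenile_prop,
                 seasonal_modifiers = seasonal_modifiers,
                 covariate_effects = covariate_effects),
            class = "agent_config")
}

archetype_levels <- function() c("resident", "continuous", "periodic", "rare")

category_levels <- function() c("resident", "continuous", "periodic", "rare")

seasonal_multiplier <- function(config, archetype, seasons) {
  mod <- config$seasonal_modifiers[[archetype]]
  out <- rep(1, length(seasons))
  if (!is.null(mod)) {
    for (s in names(mod)) out[seasons == s] <- mod[[s]]
  }
  out
}

#' Simulate daily presence of the population
#'
#' Draws, for every bird and every calendar day, whether the bird is
#' present in the study area, according to its archetype process and the
#' seasonal multipliers of its configuration.
#'
#' @param agents an [agent_config()].
#' @param calendar a vector of `Date`s (at least 30 days).
#' @param seed integer seed.
#' @return A logical matrix (birds x days, dimnames bird id / ISO date)
#'   with attribute `birds`: a data frame `bird_id`, `marked`, `archetype`,
#'   `age_class`.
#' @export
simulate_presence <- function(agents, calendar, seed = 1L) {
  stopifnot(inherits(agents, "agent_config"))
  calendar <- as.Date(calendar)
  if (length(calendar) < 30L) stop("calendar must span at least 30 days")
  set.seed(as.integer(seed))
  nd <- length(calendar)
  seasons <- assign_season(calendar)

  draw_pop <- function(n, mix, prefix, marked) {
    if (n == 0L) return(NULL)
    counts <- round_mix(n, mix)
    data.frame(
      bird_id = sprintf("%s%03d", prefix, seq_len(n)),
      marked = marked,
      archetype = rep(archetype_levels(), counts),
      age_class = ifelse(stats::runif(n) < agents$age_juvenile_prop,
                         "juvenile", "nonjuvenile"),
      stringsAsFactors = FALSE
    )
  }
  birds <- rbind(draw_pop(agents$n_marked, agents$archetype_mix, "M", 1L),
                 draw_pop(agents$n_unmarked, agents$unmarked_mix, "U", 0L))
  nb <- nrow(birds)
  pres <- matrix(FALSE, nb, nd,
                 dimnames = list(birds$bird_id, format(calendar)))
  for (i in seq_len(nb)) {
    a <- birds$archetype[i]
    mult <- seasonal_multiplier(agents, a, seasons)
    if (a == "resident") {
      p <- pmin(1, agents$p_resident * mult)
      pres[i, ] <- stats::runif(nd) < p
    } else if (a == "continuous") {
      p <- pmin(1, agents$p_continuous * mult)
      pres[i, ] <- stats::runif(nd) < p
    } else if (a == "periodic") {
      on <- periodic_on_mask(nd, agents$periodic_on_mean,
                             agents$periodic_off_mean,
                             agents$periodic_block_size)
      p <- pmin(1, agents$p_periodic_on * mult)
      pres[i, ] <- on & (stats::runif(nd) < p)
    } else { # rare
      if (stats::runif(1) < agents$rare_site_fidelity &&
          agents$rare_mean_days > 0) {
        k <- min(nd, 1L + stats::rpois(1, max(agents$rare_mean_days - 1, 0)))
        pres[i, sample.int(nd, k)] <- TRUE
      }
    }
  }
  attr(pres, "birds") <- birds
  pres
}

# split n into archetype counts proportional to mix (largest remainder)
round_mix <- function(n, mix) {
  raw <- n * mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1L
  }
  as.integer(counts)
}

# alternating off/on blocks; lengths 1 + nbinom(mu-1, size), random
# initial phase; size = 1 is close to the geometric default
periodic_on_mask <- function(nd, on_mean, off_mean, size = 1) {
  on <- logical(0)
  state <- stats::runif(1) < on_mean / (on_mean + off_mean)
  while (length(on) < nd) {
    m <- if (state) on_mean else off_mean
    len <- 1L + stats::rnbinom(1, mu = m - 1, size = size)
    on <- c(on, rep(state, len))
    state <- !state
  }
  on[seq_len(nd)]
}
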