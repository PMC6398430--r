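#' Run configuration for the full analysis pipeline
#'
#' @param seed top-level seed; per-stage seeds are derived as
#'   `seed + 10, seed + 20, ...` (documented, all below 2^31).
#' @param min_days rare-visitor threshold for the classifier.
#' @param k number of clusters.
#' @param radius subgroup association radius (metres).
#' @param n_boot bootstrap iterations of the seasonal battery.
#' @param sample_size day-triplets per bootstrap iteration.
#' @param alpha_wilcoxon,alpha_subgroup Bonferroni levels.
#' @param flock_family,subgroup_family count-model families.
#' @param subgroup_terms candidate terms of the subgroup models (default:
#'   a five-term set; [subgroup_candidate_terms()] gives the full ten).
#' @param stages character vector of stages to run (subset of
#'   `estimate`, `classify`, `subgroups`, `seasontests`, `avgmodel`).
#' @param detection per-session detection probability of the generator.
#' @param world_cfg,agents generator configurations.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, min_days = 5L, k = 3L, radius = 5,
                       n_boot = 2000L, sample_size = 38L,
                       alpha_wilcoxon = 0.017, alpha_subgroup = 0.008,
                       flock_family = "poisson", subgroup_family = "nbinom",
                       subgroup_terms = c("weather", "temperature",
                                          "transect_time", "season",
                                          "forested"),
                       stages = c("estimate", "classify", "subgroups",
                                  "seasontests", "avgmodel"),
                       detection = 0.5,
                       world_cfg = world_config(),
                       agents = agent_config()) {
  stopifnot(radius > 0, min_days >= 1, k >= 1, n_boot >= 1,
            sample_size >= 2)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Stages run in dependency order: simulate (when no data supplied) ->
#' estimate -> classify -> subgroups -> seasontests -> avgmodel. When
#' `out_dir` is given, every stage writes its CSV outputs there together
#' with a provenance record (seed, parameters, package version). Reruns
#' under the same configuration are reproducible.
#'
#' @param config a [run_config()].
#' @param records,sessions optional observed data (sightings + session
#'   covariates); when NULL the generator produces them.
#' @param world optional `crow_world` for barriers; generated alongside
#'   synthetic data.
#' @param out_dir optional output directory.
#' @return list of class `crow_run` with the stage results (`series`,
#'   `categories`, `subgroups`, `season_tests`, `flock_average`,
#'   `subgroup_average`, plus the inputs and `summary`).
#' @export
run_pipeline <- function(config = run_config(), records = NULL,
                         sessions = NULL, world = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  res <- list(config = config)
  if (is.null(records)) {
    sim <- simulate_sightings(config$world_cfg, config$agents,
                              detection = config$detection, seed = seed)
    records <- sim$records
    sessions <- sim$sessions
    world <- sim$world
    res$truth <- sim$truth
    res$birds <- sim$birds
  }
  if (is.null(sessions)) stop("session covariates required with observed records")
  res$records <- records
  res$sessions <- sessions
  st <- config$stages

  if ("estimate" %in% st) {
    res$series <- daily_series(records)
  }
  if ("classify" %in% st) {
    res$categories <- assign_categories(
      records, monitoring_days = unique(as.Date(sessions$date)),
      min_days = config$min_days, k = config$k)
  }
  if ("subgroups" %in% st) {
    res$subgroups <- subgroup_table(records, world, radius = config$radius)
  }
  if ("seasontests" %in% st) {
    if (is.null(res$categories)) stop("seasontests requires the classify stage")
    stab <- season_table(records, res$categories)
    res$season_props <- stab
    tests <- list()
    for (cat_ in category_levels()) {
      ok <- try(list(
        friedman = bootstrap_friedman(stab, cat_, n_boot = config$n_boot,
                                      sample_size = config$sample_size,
                                      seed = seed + 10L),
        wilcoxon = bootstrap_wilcoxon_pairs(stab, cat_,
                                            n_boot = config$n_boot,
                                            sample_size = config$sample_size,
                                            alpha = config$alpha_wilcoxon,
                                            seed = seed + 20L)), silent = TRUE)
      tests[[cat_]] <- if (inherits(ok, "try-error")) NULL else ok
    }
    rds <- relative_days_seen(records, res$categories,
                              unique(as.Date(sessions$date)))
    mc <- lapply(split(rds, rds$category), function(g) {
      if (nrow(g) < 3L) return(NULL)
      monte_carlo_friedman(as.matrix(g[season_levels()]),
                           n_resamples = config$n_boot, seed = seed + 30L)
    })
    ew <- lapply(split(rds, rds$category), function(g) {
      if (nrow(g) < 3L) return(NULL)
      exact_wilcoxon_pairs(as.matrix(g[season_levels()]),
                           alpha = config$alpha_wilcoxon)
    })
    sg_cat <- NULL
    if (!is.null(res$subgroups)) {
      sg <- res$subgroups
      cat_of <- stats::setNames(res$categories$category,
                                res$categories$bird_id)
      idx <- sg$marked == 1L & !is.na(sg$bird_id) &
        sg$bird_id %in% names(cat_of)
      if (sum(idx) > 10L) {
        sg_cat <- subgroup_size_by_category(sg$subgroup_size[idx],
                                            cat_of[sg$bird_id[idx]],
                                            alpha = config$alpha_subgroup)
      }
    }
    res$season_tests <- list(bootstrap = tests, monte_carlo = mc,
                             exact_wilcoxon = ew,
                             subgroup_by_category = sg_cat)
  }
  if ("avgmodel" %in% st) {
    if (is.null(res$series)) stop("avgmodel requires the estimate stage")
    flock_data <- prepare_flock_model_data(res$series, sessions)
    res$flock_average <- all_subsets_average(
      flock_data, flock_candidate_terms(), family = config$flock_family)
    if (!is.null(res$subgroups) && nrow(res$subgroups) > 50L) {
      sub_data <- prepare_subgroup_model_data(res$subgroups)
      res$subgroup_average <- all_subsets_average(
        sub_data, config$subgroup_terms, family = config$subgroup_family)
    }
  }
  res$summary <- summarize_population(records, res$categories)
  class(res) <- "crow_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sightings(res$records, file.path(out_dir, "sightings.csv"))
  utils::write.csv(res$sessions, file.path(out_dir, "sessions.csv"),
                   row.names = FALSE)
  if (!is.null(res$truth)) {
    utils::write.csv(res$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$series)) {
    utils::write.csv(as.data.frame(res$series),
                     file.path(out_dir, "daily_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(transect_series(res$series),
                     file.path(out_dir, "transect_estimates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$categories)) {
    utils::write.csv(as.data.frame(res$categories),
                     file.path(out_dir, "assignments.csv"), row.names = FALSE)
  }
  if (!is.null(res$subgroups)) {
    utils::write.csv(attr(res$subgroups, "subgroups"),
                     file.path(out_dir, "subgroups.csv"), row.names = FALSE)
  }
  if (!is.null(res$flock_average)) {
    utils::write.csv(res$flock_average$coefficients,
                     file.path(out_dir, "flock_average.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$subgroup_average)) {
    utils::write.csv(res$subgroup_average$coefficients,
                     file.path(out_dir, "subgroup_average.csv"),
                     row.names = FALSE)
  }
  cfg <- res$config
  prov <- list(seed = cfg$seed,
               parameters = cfg[c("min_days", "k", "radius", "n_boot",
                                  "sample_size", "alpha_wilcoxon",
                                  "alpha_subgroup", "detection")],
               stages = cfg$stages,
               package_version = as.character(utils::packageVersion("crowflock")),
               r_version = R.version.string,
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Descriptive population summary
#'
#' The headline descriptive numbers of a monitoring campaign: marked
#' birds resighted (count and percentage, rounded to the nearest
#' integer), the identification rate among marked sightings (one
#' decimal), transects per day, and per-category counts.
#'
#' @param records sightings data frame.
#' @param assignments optional category assignments.
#' @param marked_total optional number of ringed birds in the population
#'   (defaults to the number of distinct identified marked birds, a lower
#'   bound when never-seen birds exist).
#' @return list of class `crow_summary`.
#' @export
summarize_population <- function(records, assignments = NULL,
                                 marked_total = NULL) {
  records$date <- as.Date(records$date)
  idd <- records$marked == 1L & !is.na(records$bird_id)
  resighted <- length(unique(records$bird_id[idd]))
  if (is.null(marked_total)) marked_total <- resighted
  marked_sightings <- sum(records$marked == 1L)
  identified <- sum(idd)
  tpd <- tapply(records$session, records$date,
                function(s) length(unique(s)))
  cat_counts <- if (!is.null(assignments)) {
    table(factor(assignments$category, levels = category_levels()))
  } else NULL
  structure(list(
    marked_total = marked_total,
    resighted = resighted,
    resighted_pct = if (marked_total > 0)
      round(100 * resighted / marked_total) else 0,
    marked_sightings = marked_sightings,
    identified_sightings = identified,
    identification_rate = if (marked_sightings > 0)
      round(100 * identified / marked_sightings, 1) else NA_real_,
    n_observation_days = length(unique(records$date)),
    n_transects = nrow(unique(records[c("date", "session")])),
    transects_per_day_mean = if (length(tpd)) mean(tpd) else NA_real_,
    transects_per_day_sd = if (length(tpd) > 1) stats::sd(tpd) else NA_real_,
    category_counts = cat_counts), class = "crow_summary")
}

#' @export
print.crow_summary <- function(x, ...) {
  cat("Population summary\n")
  cat(sprintf("  marked birds: %d, resighted: %d (%d%%)\n",
              x$marked_total, x$resighted, x$resighted_pct))
  cat(sprintf("  identification rate: %.1f%% (%d of %d marked sightings)\n",
              x$identification_rate, x$identified_sightings,
              x$marked_sightings))
  cat(sprintf("  %d observation days, %d transects (%.2f +- %.2f per day)\n",
              x$n_observation_days, x$n_transects,
              x$transects_per_day_mean,
              ifelse(is.na(x$transects_per_day_sd), 0, x$transects_per_day_sd)))
  if (!is.null(x$category_counts)) {
    cat("  presence categories:\n")
    print(x$category_counts)
  }
  invisible(x)
}

#' @export
print.crow_run <- function(x, ...) {
  cat("<crow_run>\n")
  if (!is.null(x$series)) {
    cat(sprintf("  %d days, mean CF %.3f, mean FS_e %.1f\n",
                nrow(x$series), mean(x$series$CF), mean(x$series$FS_e)))
  }
  if (!is.null(x$categories)) {
    tb <- table(factor(x$categories$category, levels = category_levels()))
    cat("  categories:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$subgroups)) {
    g <- attr(x$subgroups, "subgroups")
    cat(sprintf("  subgroups: %d (mean size %.2f)\n", nrow(g), mean(g$size)))
  }
  invisible(x)
}
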