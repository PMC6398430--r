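# Independent oracles and shared study configurations for the test suite.

# naive agglomerative complete-linkage: returns the partition at k clusters
oracle_complete_linkage <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    bestd <- Inf
    best <- c(NA_integer_, NA_integer_)
    m <- length(clusters)
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  isTRUE(all(outer(a, a, "==") == outer(b, b, "==")))
}

# connected components by boolean transitive closure (matrix powers)
oracle_components <- function(edges, n) {
  A <- diag(n) > 0
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- TRUE
      A[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  keys <- apply(A, 1, paste, collapse = "")
  match(keys, unique(keys))
}

# the well-separated three-archetype cohort used for classifier recovery
well_separated_agents <- function(n = 80L) {
  agent_config(
    n_marked = n, n_unmarked = 0L,
    archetype_mix = c(resident = 1 / 3, continuous = 1 / 3,
                      periodic = 1 / 3, rare = 0),
    p_resident = 0.85, p_continuous = 0.30,
    periodic_on_mean = 25, periodic_off_mean = 80,
    p_periodic_on = 0.8, periodic_block_size = 50,
    seasonal_modifiers = list())
}

category_agreement <- function(seed) {
  sim <- simulate_sightings(agents = well_separated_agents(),
                            detection = 1, seed = seed, id_failure = 0)
  cats <- assign_categories(sim$records,
                            unique(as.Date(sim$sessions$date)))
  truth <- stats::setNames(sim$birds$archetype, sim$birds$bird_id)
  elig <- cats$bird_id[cats$category != "rare"]
  mean(cats$category[match(elig, cats$bird_id)] == truth[elig])
}

# marked-dominated, high-detection study in which the conservative
# estimator should be near-unbiased (see vignette)
recovery_sim <- function(seed) {
  simulate_sightings(
    world_config(summer_sessions = FALSE),
    agent_config(n_marked = 110L, n_unmarked = 11L,
                 archetype_mix = c(resident = 1, continuous = 0,
                                   periodic = 0, rare = 0),
                 unmarked_mix = c(resident = 1, continuous = 0,
                                  periodic = 0, rare = 0),
                 p_resident = 0.6, seasonal_modifiers = list()),
    detection = 0.85, seed = seed, id_failure = 0)
}

# a synthetic day-proportion table with independent season pools
null_season_table <- function(n_per_season = 38L, mean = 0.5, sd = 0.1) {
  data.frame(season = rep(crowflock:::season_levels(), each = n_per_season),
             prop_resident = stats::rnorm(3L * n_per_season, mean, sd))
}

# small sightings frame builder for hand examples
make_records <- function(date, session, bird_id, marked, n = length(bird_id),
                         x = seq_len(n), y = 0) {
  data.frame(date = as.Date(date), session = session, bird_id = bird_id,
             marked = marked, age_class = "nonjuvenile", flying = 0L,
             x_m = x, y_m = y, zone_id = "z", forested = "out_of_forest",
             on_building = "off_building", food = "grass",
             weather = "sun", temperature = "warm", visitors = "few",
             stringsAsFactors = FALSE)
}
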