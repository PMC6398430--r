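test_that("generator is deterministic under a fixed seed", {
  a <- simulate_sightings(seed = 3)
  b <- simulate_sightings(seed = 3)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$presence, b$presence)
  c <- simulate_sightings(seed = 4)
  expect_false(identical(a$records, c$records))
})

test_that("single zone without barriers leaves every sight line open", {
  z <- default_zones()[1, ]
  w <- generate_world(world_config(zones = z, barriers = empty_barriers <-
                                     data.frame(x1 = numeric(), y1 = numeric(),
                                                x2 = numeric(), y2 = numeric())))
  set.seed(1)
  pts <- cbind(runif(20, z$xmin, z$xmax), runif(20, z$ymin, z$ymax))
  for (i in 1:19) {
    expect_true(crowflock:::has_line_of_sight(pts[i, ], pts[i + 1, ],
                                              w$barriers))
  }
})

test_that("every simulated position maps to exactly one zone", {
  sim <- simulate_sightings(seed = 11)
  zid <- crowflock:::locate_zone(sim$records$x_m, sim$records$y_m, sim$world)
  expect_false(anyNA(zid))
  # interior grid points also land in a single zone (first-listed precedence)
  z <- sim$world$zones
  gx <- seq(min(z$xmin) + 0.5, max(z$xmax) - 0.5, length.out = 25)
  gy <- seq(min(z$ymin) + 0.5, max(z$ymax) - 0.5, length.out = 25)
  g <- expand.grid(x = gx, y = gy)
  expect_false(anyNA(crowflock:::locate_zone(g$x, g$y, sim$world)))
})

test_that("resident birds with daily presence one are present every day", {
  ag <- agent_config(n_marked = 10, n_unmarked = 0,
                     archetype_mix = c(resident = 1, continuous = 0,
                                       periodic = 0, rare = 0),
                     p_resident = 1, seasonal_modifiers = list())
  cal <- as.Date("2014-01-01") + 0:99
  pres <- simulate_presence(ag, cal, seed = 2)
  expect_true(all(pres))
  expect_identical(dim(pres), c(10L, 100L))
})

test_that("rare archetype days present match the configured expectation", {
  ag <- agent_config(n_marked = 200, n_unmarked = 0,
                     archetype_mix = c(resident = 0, continuous = 0,
                                       periodic = 0, rare = 1),
                     rare_mean_days = 2, rare_site_fidelity = 1,
                     seasonal_modifiers = list())
  cal <- as.Date("2014-01-01") + 0:364
  pres <- simulate_presence(ag, cal, seed = 5)
  m <- mean(rowSums(pres))
  expect_gte(m, 1)
  expect_lte(m, 3)
})

test_that("archetype mean days present lies within 3 SE of expectation", {
  ag <- agent_config(n_marked = 100, n_unmarked = 0,
                     archetype_mix = c(resident = 0, continuous = 1,
                                       periodic = 0, rare = 0),
                     p_continuous = 0.15, seasonal_modifiers = list())
  cal <- as.Date("2014-01-01") + 0:199
  pres <- simulate_presence(ag, cal, seed = 6)
  expected <- 0.15 * 200
  se <- sqrt(200 * 0.15 * 0.85) / sqrt(100)
  expect_lt(abs(mean(rowSums(pres)) - expected), 3 * se)
})

test_that("periodic birds show contiguous absence blocks", {
  ag <- agent_config(n_marked = 20, n_unmarked = 0,
                     archetype_mix = c(resident = 0, continuous = 0,
                                       periodic = 1, rare = 0),
                     p_periodic_on = 1, periodic_on_mean = 20,
                     periodic_off_mean = 40, periodic_block_size = 50,
                     seasonal_modifiers = list())
  cal <- as.Date("2014-01-01") + 0:299
  pres <- simulate_presence(ag, cal, seed = 7)
  long_absent <- vapply(seq_len(nrow(pres)), function(i) {
    r <- rle(as.vector(pres[i, ]))
    any(!r$values & r$lengths >= 10)
  }, logical(1))
  expect_gt(mean(long_absent), 0.9)
})

test_that("certain detection records every present bird exactly once", {
  ag <- agent_config(n_marked = 10, n_unmarked = 0,
                     archetype_mix = c(resident = 1, continuous = 0,
                                       periodic = 0, rare = 0),
                     p_resident = 1, seasonal_modifiers = list())
  w <- generate_world(world_config())
  w$sessions <- w$sessions[1, , drop = FALSE]   # a single transect
  pres <- simulate_presence(ag, w$calendar, seed = 8)
  cov <- simulate_covariates(w$sessions, seed = 9)
  sim <- simulate_transects(w, pres, cov, detection = 1, id_failure = 0,
                            seed = 10)
  expect_identical(nrow(sim$records), 10L)
  expect_identical(sort(sim$records$bird_id), sort(rownames(pres)))
  expect_true(all(table(sim$records$bird_id) == 1L))
})

test_that("mean records per session matches the binomial detection oracle", {
  ag <- agent_config(n_marked = 100, n_unmarked = 0,
                     archetype_mix = c(resident = 1, continuous = 0,
                                       periodic = 0, rare = 0),
                     p_resident = 1, seasonal_modifiers = list())
  sim <- simulate_sightings(agents = ag, detection = 0.5, seed = 12,
                            id_failure = 0)
  per_session <- table(paste(sim$records$date, sim$records$session))
  n_sessions <- nrow(sim$world$sessions)
  expect_identical(length(per_session), n_sessions)  # no empty sessions here
  se <- sqrt(100 * 0.25) / sqrt(n_sessions)
  expect_lt(abs(mean(per_session) - 50), 3 * se)
})

test_that("zero grouping propensity yields sparse, ungrouped placements", {
  ag <- agent_config(n_marked = 10, n_unmarked = 0,
                     archetype_mix = c(resident = 1, continuous = 0,
                                       periodic = 0, rare = 0),
                     p_resident = 1, seasonal_modifiers = list())
  sim <- simulate_sightings(agents = ag, detection = 1, seed = 13,
                            id_failure = 0, flying_prob = 0,
                            grouping = c(juvenile = 0, nonjuvenile = 0))
  skey <- paste(sim$records$date, sim$records$session)
  sessions <- unique(skey)[1:30]
  ok <- vapply(sessions, function(s) {
    p <- sim$records[skey == s, c("x_m", "y_m")]
    min(stats::dist(p)) > 5
  }, logical(1))
  # spatial oracle: 10 uniform birds on 60000 m^2 give ~0.06 expected
  # close pairs per session, so >= 80% of sessions should have none
  expect_gte(mean(ok), 0.8)
})

test_that("records carry covariates and the emitted truth matches presence", {
  sim <- simulate_sightings(seed = 14)
  expect_false(anyNA(sim$records$weather))
  expect_false(anyNA(sim$records$temperature))
  expect_false(anyNA(sim$records$visitors))
  expect_true(all(sim$records$bird_id[sim$records$marked == 0L] %in% NA))
  mon <- format(sim$world$monitoring_days)
  expect_identical(sim$truth$true_flock_size,
                   as.integer(colSums(sim$presence[, mon])))
})
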