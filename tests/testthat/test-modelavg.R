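test_that("model enumeration covers every subset deterministically", {
  expect_length(enumerate_models(flock_candidate_terms()), 32L)
  expect_length(enumerate_models(subgroup_candidate_terms()), 1024L)
  e <- enumerate_models(character(0))
  expect_length(e, 1L)
  expect_identical(e[[1]], character(0))
  expect_identical(enumerate_models(c("a", "b")),
                   list(character(0), "a", "b", c("a", "b")))
})

test_that("Akaike weights follow the closed form and its invariances", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(akaike_weights(rep(250, 4)), rep(0.25, 4))
  set.seed(2)
  a <- runif(20, 100, 200)
  expect_lt(abs(sum(akaike_weights(a)) - 1), 1e-12)
  expect_equal(akaike_weights(a), akaike_weights(a + 1234.5),
               tolerance = 1e-12)
  # overflow safety
  expect_equal(akaike_weights(c(1e8, 1e8 + 2)),
               akaike_weights(c(0, 2)), tolerance = 1e-12)
})

fake_fit <- function(terms, names, est, se, aic = 100, converged = TRUE) {
  structure(list(terms = terms,
                 coef = data.frame(name = names,
                                   term = names,
                                   estimate = est, se = se,
                                   stringsAsFactors = FALSE),
                 aic = aic, loglik = -aic / 2, converged = converged),
            class = "crow_fit")
}

test_that("full averaging matches the hand-evaluated formula", {
  m1 <- fake_fit("x", "x", 1, 0)
  m2 <- fake_fit(character(0), character(0), numeric(0), numeric(0))
  avg <- full_average(list(m1, m2), weights = c(0.5, 0.5))
  row <- avg$coefficients[avg$coefficients$name == "x", ]
  expect_equal(row$estimate, 0.5)
  expect_equal(row$se, 0.5)   # sqrt(.5*(1-.5)^2 + .5*(0-.5)^2)
})

test_that("averaging degenerate and limiting cases", {
  m1 <- fake_fit("x", "x", 0.8, 0.1, aic = 10)
  m2 <- fake_fit("x", "x", 0.8, 0.1, aic = 12)
  avg <- full_average(list(m1, m2))
  row <- avg$coefficients[avg$coefficients$name == "x", ]
  expect_equal(row$estimate, 0.8)
  expect_equal(row$se, 0.1)
  # weights concentrated on one model reproduce that model
  m3 <- fake_fit("x", "x", 2, 0.3)
  avg2 <- full_average(list(m1, m3), weights = c(1 - 1e-12, 1e-12))
  row2 <- avg2$coefficients[avg2$coefficients$name == "x", ]
  expect_equal(row2$estimate, 0.8, tolerance = 1e-9)
  expect_equal(row2$se, 0.1, tolerance = 1e-6)
  # nonconverged models are dropped with a message
  bad <- fake_fit("x", "x", 99, 1, converged = FALSE)
  expect_message(avg3 <- full_average(list(m1, m2, bad)), "nonconverged")
  expect_identical(avg3$n_models, 2L)
  expect_error(full_average(list(bad)), "no converged models")
})

test_that("intercept-only Poisson fit recovers the closed form", {
  d <- data.frame(response = rep(3L, 40),
                  date = factor(rep(sprintf("d%02d", 1:8), 5)))
  f <- fit_count_model(character(0), d, family = "poisson", random = FALSE)
  expect_true(f$converged)
  expect_equal(f$coef$estimate[1], log(3), tolerance = 1e-6)
})

test_that("a known log-linear effect is recovered within 3 SE", {
  d <- simulate_model_table(2000, effects = list(age_class =
                                                   c(nonjuvenile = 0.5)),
                            intercept = 1, factors = "age_class",
                            random_sd = 0.1, seed = 4)
  f <- fit_count_model("age_class", d, family = "poisson")
  expect_true(f$converged)
  row <- f$coef[f$coef$name == "age_classnonjuvenile", ]
  expect_lt(abs(row$estimate - 0.5), 3 * row$se)
})

test_that("adding a term never decreases the log-likelihood", {
  d <- simulate_model_table(500, intercept = 1.2,
                            factors = c("weather", "visitors"), seed = 6)
  f0 <- fit_count_model(character(0), d, family = "poisson", random = FALSE)
  f1 <- fit_count_model("weather", d, family = "poisson", random = FALSE)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("glmmTMB fits agree with the lme4 reference on a Poisson GLMM", {
  skip_if_not_installed("lme4")
  d <- simulate_model_table(800, effects = list(weather = c(clouds = 0.2,
                                                            sun = 0.35)),
                            intercept = 1.5, factors = "weather",
                            random_sd = 0.15, seed = 8)
  ours <- fit_count_model("weather", d, family = "poisson")
  ref <- lme4::glmer(response ~ weather + (1 | date), data = d,
                     family = stats::poisson())
  expect_equal(ours$coef$estimate,
               unname(lme4::fixef(ref)), tolerance = 1e-3)
})

test_that("model tables apply the documented response conventions", {
  rec <- make_records(date = "2014-05-01", session = "Morning",
                      bird_id = c("A", "B", rep(NA, 5)),
                      marked = c(1L, 1L, rep(0L, 5)))
  fs <- daily_series(rec)
  cov <- data.frame(date = as.Date("2014-05-01"), session = "Morning",
                    weather = "sun", temperature = "warm", visitors = "few")
  md <- prepare_flock_model_data(fs, cov)
  expect_identical(md$response, as.integer(round(transect_series(fs)$FS_e_t)))
  expect_identical(levels(md$weather)[1], "rain")
  expect_identical(levels(md$season)[1], "nonbreeder")
  # missing covariates for a session are a hard error
  cov2 <- cov; cov2$session <- "Afternoon"
  expect_error(prepare_flock_model_data(fs, cov2), "missing covariates")
  # subgroup response is size minus one; unknown levels are rejected
  sg <- subgroup_table(rec)
  md2 <- prepare_subgroup_model_data(sg)
  expect_identical(md2$response, sg$subgroup_size - 1L)
  sg$weather <- "drizzle"
  expect_error(prepare_subgroup_model_data(sg), "valid levels")
})

test_that("all-subsets averaging runs end to end on a small candidate set", {
  d <- simulate_model_table(600, effects = list(weather = c(clouds = 0.2,
                                                            sun = 0.4)),
                            intercept = 1, factors = c("weather", "visitors"),
                            random_sd = 0.05, seed = 10)
  avg <- all_subsets_average(d, c("weather", "visitors"), family = "poisson")
  expect_identical(avg$n_models, 4L)
  expect_lt(abs(sum(avg$weights) - 1), 1e-12)
  expect_true(all(c("weathersun", "visitorsmany") %in%
                    avg$coefficients$name))
  expect_identical(nrow(attr(avg, "aic_table")), 4L)
  expect_s3_class(avg, "crow_model_average")
  expect_named(coef(avg))
})
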