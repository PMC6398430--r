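test_that("season assignment follows the breeding-ecology partition", {
  expect_identical(assign_season(as.Date("2014-03-15")), "breeding")
  expect_identical(assign_season(as.Date("2014-06-01")), "parental_care")
  expect_identical(assign_season(as.Date("2015-01-31")), "nonbreeder")
  # every calendar date maps to exactly one season
  yr <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  s <- assign_season(yr)
  expect_true(all(s %in% c("breeding", "parental_care", "nonbreeder")))
  expect_identical(unname(table(s)["breeding"]), 120L)  # Feb-May 2014
})

test_that("fast Friedman statistic equals stats::friedman.test", {
  set.seed(9)
  for (i in 1:8) {
    M <- matrix(sample(1:6, 30, replace = TRUE), 10, 3)
    expect_equal(crowflock:::friedman_chisq(M),
                 unname(friedman.test(M)$statistic))
  }
  M4 <- matrix(rnorm(28), 7, 4)
  expect_equal(crowflock:::friedman_chisq(M4),
               unname(friedman.test(M4)$statistic))
})

test_that("bootstrap Friedman: null identity, determinism, convergence", {
  # identical proportions across seasons and days
  flat <- data.frame(season = rep(crowflock:::season_levels(), each = 38),
                     prop_resident = 0.5)
  r <- bootstrap_friedman(flat, "resident", n_boot = 500, seed = 1)
  expect_equal(r$statistic_mean, 0)
  expect_equal(r$p_mean, 1)
  # determinism
  set.seed(99); tab <- null_season_table()
  a <- bootstrap_friedman(tab, "resident", n_boot = 300, seed = 5)
  b <- bootstrap_friedman(tab, "resident", n_boot = 300, seed = 5)
  expect_identical(a, b)
  # mean p drift between 5000 and 10000 iterations on a fixed dataset
  r5 <- bootstrap_friedman(tab, "resident", n_boot = 5000, seed = 7)
  r10 <- bootstrap_friedman(tab, "resident", n_boot = 10000, seed = 7)
  expect_lt(abs(r5$p_mean - r10$p_mean), 0.005)
})

test_that("bootstrap Wilcoxon pairs: identity, symmetry and power", {
  flat <- data.frame(season = rep(crowflock:::season_levels(), each = 38),
                     prop_resident = 0.4)
  w <- suppressWarnings(
    bootstrap_wilcoxon_pairs(flat, "resident", n_boot = 200, seed = 2))
  expect_equal(w[[1]]$p_mean, 1)
  expect_false(w[[1]]$significant)
  # swapping two seasons leaves p unchanged and mirrors V
  set.seed(11)
  tab <- null_season_table()
  tab$prop_resident[tab$season == "breeding"] <-
    tab$prop_resident[tab$season == "breeding"] + 0.08
  swap <- tab
  swap$season[tab$season == "nonbreeder"] <- "breeding"
  swap$season[tab$season == "breeding"] <- "nonbreeder"
  w1 <- bootstrap_wilcoxon_pairs(tab, "resident", n_boot = 400, seed = 3)
  w2 <- bootstrap_wilcoxon_pairs(swap, "resident", n_boot = 400, seed = 3)
  pair <- "nonbreeder/breeding"
  # season roles reversed: p agrees and V mirrors about n(n+1)/4, up to
  # Monte-Carlo error of the two independent resampling runs
  expect_lt(abs(w1[[pair]]$p_mean - w2[[pair]]$p_mean), 0.03)
  expect_lt(abs(w1[[pair]]$statistic_mean + w2[[pair]]$statistic_mean -
                  38 * 39 / 2), 15)
  # power at a strong configured shift
  rej <- vapply(1:25, function(i) {
    set.seed(1000 + i)
    t2 <- null_season_table()
    t2$prop_resident[t2$season == "breeding"] <-
      t2$prop_resident[t2$season == "breeding"] + 0.15
    ww <- bootstrap_wilcoxon_pairs(t2, "resident", n_boot = 50,
                                   seed = 2000 + i)
    ww[[pair]]$significant
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("Monte-Carlo Friedman agrees with exhaustive enumeration", {
  M <- rbind(c(1.0, 2.0, 3.0),
             c(2.5, 1.0, 3.5),
             c(1.5, 3.0, 2.0),
             c(3.0, 2.5, 1.0))
  obs <- crowflock:::friedman_chisq(M)
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6))
  ptab <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stats_all <- apply(perms, 1, function(pp) {
    M2 <- t(vapply(1:4, function(b) M[b, ptab[pp[b], ]], numeric(3)))
    crowflock:::friedman_chisq(M2)
  })
  p_exact <- mean(stats_all >= obs - 1e-12)
  mc <- monte_carlo_friedman(M, n_resamples = 20000, seed = 8)
  expect_equal(mc$chisq, obs)
  expect_lt(abs(mc$p - p_exact), 0.02)
  # constant blocks
  flatmc <- monte_carlo_friedman(matrix(1, 5, 3), n_resamples = 100, seed = 1)
  expect_identical(flatmc$chisq, 0)
  expect_equal(flatmc$p, 1)
  # determinism
  expect_identical(monte_carlo_friedman(M, 500, seed = 4),
                   monte_carlo_friedman(M, 500, seed = 4))
})

test_that("exact signed-rank test matches enumeration and wilcox.test", {
  # 5 all-positive differences: one-sided 1/32, two-sided 1/16
  w <- signed_rank_test(c(1, 2, 3, 4, 5), method = "exact")
  expect_identical(w$V, 15)
  expect_equal(w$p, 1 / 16)
  # antisymmetry under sign flip
  w2 <- signed_rank_test(-c(1, 2, 3, 4, 5), method = "exact")
  expect_equal(w2$p, w$p)
  expect_identical(w2$V, 0)
  # all zero differences
  expect_warning(w0 <- signed_rank_test(rep(0, 4)), "zero")
  expect_true(is.na(w0$p))
  # cross-check against the reference implementation (no ties)
  set.seed(13)
  for (i in 1:8) {
    d <- rnorm(sample(6:20, 1))
    ours <- signed_rank_test(d, method = "exact")
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$V, unname(ref$statistic))
  }
  # exact DP handles midranks (ties) by full sign enumeration
  d <- c(1, 1, 2, -2, 3)
  r <- rank(abs(d))
  Vs <- vapply(0:31, function(mask) {
    sgn <- ifelse(bitwAnd(mask, 2^(0:4)) > 0, 1, -1)
    sum(r[sgn > 0])
  }, numeric(1))
  obsV <- sum(r[d > 0])
  p_enum <- min(1, 2 * min(mean(Vs <= obsV), mean(Vs >= obsV)))
  expect_equal(signed_rank_test(d, method = "exact")$p, p_enum)
})

test_that("exact Wilcoxon pairs table flags by the Bonferroni level", {
  set.seed(21)
  M <- cbind(nonbreeder = rnorm(12, 0.5, 0.05),
             breeding = rnorm(12, 0.2, 0.05),
             parental_care = rnorm(12, 0.5, 0.05))
  res <- exact_wilcoxon_pairs(M, alpha = 0.017)
  expect_identical(nrow(res), 3L)
  expect_true(res$significant[res$pair == "nonbreeder/breeding"])
  expect_false(res$significant[res$pair == "nonbreeder/parental_care"])
})

test_that("subgroup sizes across categories: U example and invariances", {
  r <- subgroup_size_by_category(c(1, 2, 3, 4, 5, 6),
                                 rep(c("a", "b"), each = 3), alpha = 0.008)
  expect_identical(unname(r$pairwise$W), 0)
  same <- subgroup_size_by_category(rep(c(1, 2, 3), 4),
                                    rep(c("a", "b"), each = 6))
  expect_lt(same$omnibus$H, 1e-9)
  expect_true(all(same$pairwise$p > 0.5))
  # rank invariance under a monotone transform
  set.seed(5)
  sizes <- sample(1:10, 40, replace = TRUE)
  cats <- sample(c("w", "x", "y", "z"), 40, replace = TRUE)
  h1 <- subgroup_size_by_category(sizes, cats)$omnibus$H
  h2 <- subgroup_size_by_category(exp(sizes), cats)$omnibus$H
  expect_equal(h1, h2)
})
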