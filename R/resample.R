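#' Friedman chi-squared statistic (tie-corrected)
#'
#' Rank-based statistic for `k` related samples in `n` blocks (rows),
#' with the usual tie correction; equals the statistic of
#' [stats::friedman.test()]. A fast closed-form path handles the
#' three-column case used throughout the seasonal battery.
#'
#' @param M numeric matrix, blocks x treatments.
#' @return the chi-squared statistic (df = k - 1).
#' @keywords internal
friedman_chisq <- function(M) {
  n <- nrow(M); k <- ncol(M)
  if (k == 3L) {
    x1 <- M[, 1]; x2 <- M[, 2]; x3 <- M[, 3]
    r1 <- 1 + (x2 < x1) + (x3 < x1) + 0.5 * ((x2 == x1) + (x3 == x1))
    r2 <- 1 + (x1 < x2) + (x3 < x2) + 0.5 * ((x1 == x2) + (x3 == x2))
    r3 <- 1 + (x1 < x3) + (x2 < x3) + 0.5 * ((x1 == x3) + (x2 == x3))
    S <- (sum(r1) - n * 2)^2 + (sum(r2) - n * 2)^2 + (sum(r3) - n * 2)^2
    ties <- sum(((x1 == x2) & (x2 == x3)) * 24 +
                ((x1 == x2) & (x1 != x3)) * 6 +
                ((x1 == x3) & (x1 != x2)) * 6 +
                ((x2 == x3) & (x1 != x2)) * 6)
    den <- n * k * (k + 1) - ties / (k - 1)
    return(if (den <= 0) 0 else 12 * S / den)
  }
  r <- t(apply(M, 1L, rank))
  ties <- sum(unlist(lapply(seq_len(n), function(i) {
    tt <- table(r[i, ]); sum(tt^3 - tt)
  })))
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) return(0)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / den
}

#' Wilcoxon signed-rank statistic and p-value
#'
#' Zero differences are dropped (Wilcoxon's original rule, matching the
#' exact enumeration). `method = "exact"` computes the null distribution
#' of the rank sum by shifted convolution over (doubled) midranks --
#' exact also under ties; `"approx"` uses the tie-corrected normal
#' approximation with continuity correction; `"auto"` picks exact for
#' n <= 25 without ties.
#'
#' @param d numeric vector of paired differences.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return list `V`, `p` (two-sided), `n` (nonzero differences),
#'   `method`.
#' @export
signed_rank_test <- function(d, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences zero; no signed-rank test possible")
    return(list(V = NA_real_, p = NA_real_, n = 0L, method = "none"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0
  if (method == "auto") method <- if (n <= 25L) "exact" else "approx"
  if (method == "exact") {
    s <- as.integer(round(2 * r))          # doubled midranks are integers
    tot <- sum(s)
    counts <- numeric(tot + 1L)            # counts[v+1] = #subsets with sum v
    counts[1L] <- 1
    for (si in s) {
      shifted <- c(numeric(si), counts[seq_len(tot + 1L - si)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(counts[seq_len(v2 + 1L)])
    p_ge <- sum(counts[seq(v2 + 1L, tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)   # continuity corr.
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(V = V, p = p, n = n, method = method)
}

new_bootstrap_result <- function(stat_name, stats_v, ps, sample_size, alpha) {
  n <- length(stats_v)
  se <- function(x) if (n > 1) stats::sd(x, na.rm = TRUE) / sqrt(n) else 0
  res <- list(statistic = stat_name,
              statistic_mean = mean(stats_v, na.rm = TRUE),
              statistic_se = se(stats_v),
              p_mean = mean(ps), p_se = se(ps),
              n_iter = n, sample_size = sample_size, alpha = alpha,
              significant = mean(ps) < alpha)
  class(res) <- "bootstrap_result"
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s = %.3f +- %.3f, P = %.4g +- %.2g (n = %d iterations%s)%s\n",
              x$statistic, x$statistic_mean, x$statistic_se,
              x$p_mean, x$p_se, x$n_iter,
              if (!is.null(x$sample_size)) paste0(", sample size ", x$sample_size) else "",
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

season_pools <- function(day_proportions, category) {
  col <- paste0("prop_", category)
  if (!col %in% names(day_proportions)) {
    stop("unknown category: ", category)
  }
  pools <- lapply(season_levels(), function(s) {
    v <- day_proportions[[col]][day_proportions$season == s]
    v[!is.na(v)]
  })
  names(pools) <- season_levels()
  if (any(lengths(pools) == 0L)) {
    stop("a season has zero days with data for category ", category)
  }
  pools
}

draw_triplets <- function(pools, sample_size, replace) {
  if (!replace) {
    short <- lengths(pools) < sample_size
    if (any(short)) {
      stop("sample_size exceeds a season's day pool; use replace = TRUE")
    }
  }
  vapply(pools, function(p) p[sample.int(length(p), sample_size,
                                         replace = replace)],
         numeric(sample_size))
}

#' Bootstrap Friedman test of a category's daily proportions across seasons
#'
#' Per iteration, `sample_size` day-triplets are drawn (one day per
#' season, paired by draw index -- days carry no natural pairing across
#' seasons) and a tie-corrected Friedman test across the three season
#' columns is computed. The mean and SE of the chi-squared statistic and
#' of the p-value over iterations are reported, and significance is
#' called by comparing the mean p to `alpha`.
#'
#' With `replace = TRUE` (the default) the days are resampled with
#' replacement (a bootstrap); `replace = FALSE` draws each day at most
#' once per iteration (a pure re-pairing permutation), which keeps every
#' iteration an exact-level test -- see the package vignette for the
#' size behaviour of the two variants.
#'
#' @param day_proportions a [season_table()].
#' @param category one of the presence categories.
#' @param n_boot iterations (default 10000).
#' @param sample_size day-triplets per iteration (default 38).
#' @param alpha significance level for the mean-p call (default 0.05).
#' @param seed integer seed.
#' @param replace resample days with replacement (default TRUE).
#' @return a `bootstrap_result`.
#' @export
bootstrap_friedman <- function(day_proportions, category, n_boot = 10000L,
                               sample_size = 38L, alpha = 0.05, seed = 1L,
                               replace = TRUE) {
  pools <- season_pools(day_proportions, category)
  set.seed(as.integer(seed))
  stats_v <- numeric(n_boot); ps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    M <- draw_triplets(pools, sample_size, replace)
    stats_v[b] <- friedman_chisq(M)
    ps[b] <- stats::pchisq(stats_v[b], df = 2L, lower.tail = FALSE)
  }
  new_bootstrap_result("Friedman chi-squared", stats_v, ps, sample_size, alpha)
}

#' Bootstrap pairwise Wilcoxon tests of a category's daily proportions
#'
#' The same resampling scheme as [bootstrap_friedman()], with a paired
#' two-tailed Wilcoxon signed-rank test per season pair and iteration.
#' The Bonferroni level for three pairs (`alpha = 0.017`) is applied to
#' the mean p of each pair.
#'
#' @inheritParams bootstrap_friedman
#' @param alpha Bonferroni-corrected level (default 0.017).
#' @return named list of three `bootstrap_result`s
#'   (`breeding/parental_care` etc.).
#' @export
bootstrap_wilcoxon_pairs <- function(day_proportions, category,
                                     n_boot = 10000L, sample_size = 38L,
                                     alpha = 0.017, seed = 1L,
                                     replace = TRUE) {
  pools <- season_pools(day_proportions, category)
  pairs <- utils::combn(season_levels(), 2L)
  set.seed(as.integer(seed))
  Vs <- matrix(NA_real_, n_boot, 3L)
  Ps <- matrix(NA_real_, n_boot, 3L)
  for (b in seq_len(n_boot)) {
    M <- draw_triplets(pools, sample_size, replace)
    for (j in 1:3) {
      d <- M[, pairs[1, j]] - M[, pairs[2, j]]
      w <- suppressWarnings(signed_rank_test(d, method = "approx"))
      Vs[b, j] <- w$V
      Ps[b, j] <- if (is.na(w$p)) 1 else w$p
    }
  }
  out <- lapply(1:3, function(j) {
    new_bootstrap_result("Wilcoxon V", Vs[, j], Ps[, j], sample_size, alpha)
  })
  names(out) <- apply(pairs, 2, paste, collapse = "/")
  out
}

#' Monte-Carlo (approximative) Friedman test on relative days seen
#'
#' Permutation-null Friedman test: birds are blocks with one value per
#' season; the reference distribution is generated by independent random
#' permutations within each block, and
#' \eqn{p = (1 + \#\{\chi^2_{perm} \ge \chi^2_{obs}\})/(1 + n_{resamples})}.
#'
#' @param values numeric matrix, birds x seasons (typically the three
#'   season columns of [relative_days_seen()]).
#' @param n_resamples Monte-Carlo resamples (default 10000).
#' @param seed integer seed.
#' @return list `chisq`, `p`, `n_blocks`, `n_resamples`.
#' @export
monte_carlo_friedman <- function(values, n_resamples = 10000L, seed = 1L) {
  M <- as.matrix(values)
  n <- nrow(M); k <- ncol(M)
  obs <- friedman_chisq(M)
  set.seed(as.integer(seed))
  ge <- 0L
  if (k == 3L) {
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    for (r in seq_len(n_resamples)) {
      pi <- perms[sample.int(6L, n, replace = TRUE), , drop = FALSE]
      M2 <- cbind(M[cbind(seq_len(n), pi[, 1])],
                  M[cbind(seq_len(n), pi[, 2])],
                  M[cbind(seq_len(n), pi[, 3])])
      if (friedman_chisq(M2) >= obs - 1e-12) ge <- ge + 1L
    }
  } else {
    for (r in seq_len(n_resamples)) {
      M2 <- t(apply(M, 1L, sample))
      if (friedman_chisq(M2) >= obs - 1e-12) ge <- ge + 1L
    }
  }
  list(chisq = obs, p = (1 + ge) / (1 + n_resamples),
       n_blocks = n, n_resamples = n_resamples)
}

#' Exact paired Wilcoxon signed-rank tests across season pairs
#'
#' One exact two-tailed signed-rank test per season pair on per-bird
#' values (e.g. relative days seen), with zero differences dropped and
#' the Bonferroni level applied.
#'
#' @param values numeric matrix, birds x seasons (colnames = seasons).
#' @param alpha Bonferroni-corrected level (default 0.017).
#' @return data frame: `pair`, `V`, `p`, `n`, `significant`.
#' @export
exact_wilcoxon_pairs <- function(values, alpha = 0.017) {
  M <- as.matrix(values)
  cn <- colnames(M)
  if (is.null(cn)) cn <- paste0("s", seq_len(ncol(M)))
  pairs <- utils::combn(ncol(M), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    d <- M[, pairs[1, j]] - M[, pairs[2, j]]
    w <- signed_rank_test(d, method = "exact")
    data.frame(pair = paste(cn[pairs[1, j]], cn[pairs[2, j]], sep = "/"),
               V = w$V, p = w$p, n = w$n,
               significant = !is.na(w$p) && w$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subgroup size comparisons across presence categories
#'
#' Kruskal-Wallis omnibus test (tie-corrected) of per-record subgroup
#' sizes across the four presence categories, followed by all pairwise
#' two-tailed Mann-Whitney U tests at the Bonferroni level.
#'
#' @param sizes numeric vector of per-record subgroup sizes.
#' @param categories presence category per record (same length).
#' @param alpha Bonferroni level for the pairwise tests (default 0.008).
#' @return list `omnibus` (`H`, `df`, `p`) and `pairwise` (data frame
#'   `pair`, `W`, `p`, `significant`).
#' @export
subgroup_size_by_category <- function(sizes, categories, alpha = 0.008) {
  categories <- factor(categories)
  if (nlevels(categories) < 2L) stop("need at least two categories")
  kw <- stats::kruskal.test(sizes, categories)
  levs <- levels(categories)
  pairs <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- sizes[categories == pairs[1, j]]
    b <- sizes[categories == pairs[2, j]]
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(pair = paste(pairs[1, j], pairs[2, j], sep = "/"),
               W = unname(w$statistic), p = w$p.value,
               significant = w$p.value < alpha, stringsAsFactors = FALSE)
  })
  list(omnibus = list(H = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = do.call(rbind, rows), alpha = alpha)
}
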