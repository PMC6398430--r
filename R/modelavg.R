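#' Factor level conventions of the count models
#'
#' Reference levels (first level of each factor): Morning transects,
#' nonbreeder season, cold, rain, few visitors, in forest, on building,
#' juvenile, grass food. Reported table rows are therefore the non-
#' reference levels.
#' @return named list of level vectors.
#' @export
model_factor_levels <- function() {
  list(weather = weather_levels(),
       temperature = temperature_levels(),
       transect_time = session_levels(),
       season = season_levels(),
       visitors = visitor_levels(),
       age_class = c("juvenile", "nonjuvenile"),
       forested = c("in_forest", "out_of_forest"),
       on_building = c("on_building", "off_building"),
       food = food_levels())
}

coerce_model_factor <- function(x, name) {
  levs <- model_factor_levels()[[name]]
  if (is.null(levs)) return(x)
  bad <- setdiff(unique(as.character(x)), levs)
  if (length(bad)) {
    stop("unknown level(s) ", paste(bad, collapse = ", "), " for factor '",
         name, "'; valid levels: ", paste(levs, collapse = ", "))
  }
  factor(as.character(x), levels = levs)
}

#' Model table for the flock-size models
#'
#' One row per transect: the per-transect flock size estimate rounded to
#' the nearest integer as the count response, the session covariates and
#' the season, with `date` as the grouping variable of the random
#' intercept.
#'
#' @param series a `flock_series` from [daily_series()].
#' @param covariates session covariates (`date`, `session`, `weather`,
#'   `temperature`, `visitors`).
#' @return data frame `response`, `date`, `transect_time`, `season`,
#'   `weather`, `temperature`, `visitors`.
#' @export
prepare_flock_model_data <- function(series, covariates) {
  tr <- transect_series(series)
  covariates$date <- as.Date(covariates$date)
  key <- paste(tr$date, tr$session)
  ckey <- paste(covariates$date, covariates$session)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    stop("missing covariates for session(s): ",
         paste(utils::head(key[is.na(idx)], 5), collapse = "; "))
  }
  data.frame(
    response = as.integer(round(tr$FS_e_t)),
    date = factor(format(tr$date)),
    transect_time = coerce_model_factor(tr$session, "transect_time"),
    season = coerce_model_factor(assign_season(tr$date), "season"),
    weather = coerce_model_factor(covariates$weather[idx], "weather"),
    temperature = coerce_model_factor(covariates$temperature[idx], "temperature"),
    visitors = coerce_model_factor(covariates$visitors[idx], "visitors"))
}

#' Model table for the subgroup-size models
#'
#' One row per nonflying sighting: the record's subgroup size minus one
#' as the count response (the negative binomial convention for sizes
#' starting at 1), the session covariates, habitat attributes of the
#' record's zone, the bird's age class and the number of crows recorded
#' in the session.
#'
#' @param sg a `subgroup_table`.
#' @return data frame with `response`, `date` and the ten candidate
#'   factors.
#' @export
prepare_subgroup_model_data <- function(sg) {
  need <- c("subgroup_size", "date", "session", "weather", "temperature",
            "visitors", "age_class", "forested", "on_building", "food",
            "n_crows_present")
  missing_cols <- setdiff(need, names(sg))
  if (length(missing_cols)) {
    stop("subgroup table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  data.frame(
    response = as.integer(sg$subgroup_size - 1L),
    date = factor(format(as.Date(sg$date))),
    transect_time = coerce_model_factor(sg$session, "transect_time"),
    season = coerce_model_factor(assign_season(sg$date), "season"),
    weather = coerce_model_factor(sg$weather, "weather"),
    temperature = coerce_model_factor(sg$temperature, "temperature"),
    visitors = coerce_model_factor(sg$visitors, "visitors"),
    n_crows_present = as.numeric(sg$n_crows_present),
    age_class = coerce_model_factor(sg$age_class, "age_class"),
    forested = coerce_model_factor(sg$forested, "forested"),
    on_building = coerce_model_factor(sg$on_building, "on_building"),
    food = coerce_model_factor(sg$food, "food"))
}

#' Candidate term sets of the two model families
#'
#' Five flock-size terms (2^5 = 32 models) and ten subgroup-size terms
#' (2^10 = 1024 models).
#' @return character vector of term names.
#' @export
flock_candidate_terms <- function() {
  c("weather", "temperature", "transect_time", "season", "visitors")
}

#' @rdname flock_candidate_terms
#' @export
subgroup_candidate_terms <- function() {
  c("weather", "temperature", "transect_time", "season", "visitors",
    "n_crows_present", "age_class", "forested", "food", "on_building")
}

#' Enumerate all subsets of candidate terms
#'
#' @param candidates character vector of term names.
#' @return list of 2^k character vectors (first element: the
#'   intercept-only model `character(0)`), in deterministic binary order.
#' @export
enumerate_models <- function(candidates) {
  k <- length(candidates)
  lapply(seq_len(2^k) - 1L, function(mask) {
    candidates[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L]
  })
}

#' Fit one log-link count model
#'
#' Log-link Poisson or negative binomial (quadratic parameterisation,
#' dispersion estimated by maximum likelihood) regression via
#' \pkg{glmmTMB}, with an optional date-level random intercept estimated
#' by Laplace approximation. Non-positive-definite Hessians or optimiser
#' failures are flagged as nonconverged rather than raising.
#'
#' @param terms character vector of fixed terms (may be empty).
#' @param data model table with `response` and `date`.
#' @param family `"poisson"` or `"nbinom"`.
#' @param random include the date random intercept (default TRUE).
#' @return list of class `crow_fit`: `terms`, `coef` (data frame
#'   `name`, `term`, `estimate`, `se`), `aic`, `loglik`, `converged`.
#' @export
fit_count_model <- function(terms, data, family = c("poisson", "nbinom"),
                            random = TRUE) {
  family <- match.arg(family)
  if (nrow(data) == 0L) stop("empty model table")
  if (any(data$response < 0)) stop("response must be a nonnegative count")
  rhs_fixed <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  rhs <- if (random) paste(rhs_fixed, "+ (1 | date)") else rhs_fixed
  fml <- stats::as.formula(paste("response ~", rhs))
  fam <- if (family == "poisson") stats::poisson() else glmmTMB::nbinom2()
  fit <- try(suppressWarnings(
    glmmTMB::glmmTMB(fml, data = data, family = fam)), silent = TRUE)
  bad <- inherits(fit, "try-error") ||
    !isTRUE(fit$sdr$pdHess) || fit$fit$convergence != 0
  if (inherits(fit, "try-error")) {
    return(structure(list(terms = terms, coef = NULL, aic = NA_real_,
                          loglik = NA_real_, converged = FALSE),
                     class = "crow_fit"))
  }
  est <- glmmTMB::fixef(fit)$cond
  vc <- try(stats::vcov(fit)$cond, silent = TRUE)
  se <- if (inherits(vc, "try-error")) rep(NA_real_, length(est)) else
    sqrt(diag(vc))
  # map coefficient names to their generating term
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs_fixed)), data)
  asg <- attr(mm, "assign")
  labs <- c("(Intercept)", terms)[asg + 1L]
  coef_df <- data.frame(name = names(est),
                        term = labs[match(names(est), colnames(mm))],
                        estimate = unname(est), se = unname(se),
                        stringsAsFactors = FALSE)
  structure(list(terms = terms, coef = coef_df,
                 aic = as.numeric(stats::AIC(fit)),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = !bad && all(is.finite(se))),
            class = "crow_fit")
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}; the minimum subtraction doubles as
#' overflow protection.
#'
#' @param aics numeric vector of AIC values.
#' @return numeric weights summing to one.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(aics) {
  if (any(!is.finite(aics))) stop("AIC values must be finite")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Weighted full (zero-substitution) model average
#'
#' Averages coefficients over a candidate model set: a model in which a
#' term is absent contributes estimate 0 (with zero within-model SE) at
#' that model's weight. The unconditional standard error follows
#' Burnham & Anderson,
#' \deqn{SE(\bar b) = \sqrt{\sum_i w_i \,(SE_i^2 + (b_i - \bar b)^2)},}
#' and a two-sided normal p-value is derived from \eqn{\bar b / SE}.
#'
#' @param fits list of `crow_fit` objects (nonconverged fits are dropped
#'   with a message and the weights renormalised).
#' @param weights Akaike weights aligned with `fits` (default: computed
#'   from the fits' AICs).
#' @return object of class `crow_model_average` with elements
#'   `coefficients` (data frame `name`, `term`, `estimate`, `se`, `z`,
#'   `p`), `weights`, `aic` and `n_models`.
#' @export
full_average <- function(fits, weights = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged models to average")
  if (any(!conv)) {
    message(sum(!conv), " nonconverged model(s) dropped before averaging")
  }
  fits <- fits[conv]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  if (is.null(weights)) {
    weights <- akaike_weights(aics)
  } else {
    weights <- weights[conv]
    weights <- weights / sum(weights)
  }
  cf <- do.call(rbind, lapply(seq_along(fits), function(i) {
    ci <- fits[[i]]$coef
    if (is.null(ci) || nrow(ci) == 0L) return(NULL)
    cbind(ci, model = i, w = weights[i])
  }))
  if (is.null(cf)) stop("no coefficients among the converged models")
  names_u <- unique(cf$name)
  rows <- lapply(names_u, function(nm) {
    sub <- cf[cf$name == nm, , drop = FALSE]
    b <- stats::setNames(rep(0, length(fits)), seq_along(fits))
    s <- b
    b[sub$model] <- sub$estimate
    s[sub$model] <- sub$se
    bbar <- sum(weights * b)
    se <- sqrt(sum(weights * (s^2 + (b - bbar)^2)))
    z <- if (se > 0) bbar / se else NA_real_
    data.frame(name = nm, term = sub$term[1], estimate = bbar, se = se,
               z = z, p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  structure(list(coefficients = do.call(rbind, rows),
                 weights = weights, aic = aics, n_models = length(fits)),
            class = "crow_model_average")
}

#' All-subsets count-model averaging
#'
#' Enumerates every subset of the candidate terms, fits each log-link
#' count model (with the date random intercept) and forms the weighted
#' full model average.
#'
#' @param data model table from [prepare_flock_model_data()] or
#'   [prepare_subgroup_model_data()].
#' @param candidates candidate term names (default: all non-`response`,
#'   non-`date` columns of `data`).
#' @param family `"poisson"` (flock size) or `"nbinom"` (subgroup size
#'   minus one).
#' @param random include the date random intercept.
#' @return a `crow_model_average`; the per-model AIC table is attached
#'   as attribute `aic_table`.
#' @export
all_subsets_average <- function(data, candidates = NULL,
                                family = c("poisson", "nbinom"),
                                random = TRUE) {
  family <- match.arg(family)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data), c("response", "date"))
  }
  specs <- enumerate_models(candidates)
  fits <- lapply(specs, fit_count_model, data = data, family = family,
                 random = random)
  avg <- full_average(fits)
  attr(avg, "aic_table") <- data.frame(
    model = vapply(specs, function(s)
      if (length(s)) paste(s, collapse = "+") else "1", character(1)),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  avg
}

#' @export
print.crow_model_average <- function(x, ...) {
  cat("<crow_model_average> full average over ", x$n_models,
      " models\n", sep = "")
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, 3)
  cf$se <- round(cf$se, 3)
  cf$p <- signif(cf$p, 3)
  print(cf[c("term", "name", "estimate", "se", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.crow_model_average <- function(object, ...) {
  cat("Weighted full model average (", object$n_models, " models)\n", sep = "")
  cat(sprintf("  top model weight %.3f, weight sum %.6f\n",
              max(object$weights), sum(object$weights)))
  print(object)
  invisible(object)
}

#' @export
coef.crow_model_average <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$name)
}

#' Synthetic covariate/count table with injected log-linear effects
#'
#' Generates a model table directly on the scale of the count models:
#' session covariates drawn uniformly, a date-level normal random
#' intercept, and a Poisson or negative binomial response with known
#' log-linear coefficients. Used to validate effect recovery of the
#' all-subsets average.
#'
#' @param n number of records.
#' @param effects named list per factor of named level effects (log
#'   scale), e.g. `list(weather = c(clouds = 0.15, sun = 0.3))`; levels
#'   not listed (and reference levels) have effect 0.
#' @param intercept log-scale intercept.
#' @param family `"poisson"` or `"nbinom"`.
#' @param theta negative binomial dispersion (ignored for Poisson).
#' @param random_sd SD of the date random intercept.
#' @param n_dates number of distinct dates.
#' @param factors which factors to include as columns (default: the
#'   flock candidate set).
#' @param seed integer seed.
#' @return model table (`response`, `date`, factor columns) with the true
#'   coefficient vector as attribute `truth`.
#' @export
simulate_model_table <- function(n, effects = list(),
                                 intercept = 1, family = c("poisson", "nbinom"),
                                 theta = 2, random_sd = 0.1,
                                 n_dates = 100L,
                                 factors = flock_candidate_terms(),
                                 seed = 1L) {
  family <- match.arg(family)
  set.seed(as.integer(seed))
  levs <- model_factor_levels()
  out <- data.frame(date = factor(sample(sprintf("d%03d", seq_len(n_dates)),
                                         n, replace = TRUE)))
  eta <- rep(intercept, n)
  truth <- c("(Intercept)" = intercept)
  for (f in factors) {
    if (f == "n_crows_present") {
      x <- stats::rpois(n, 20)
      out[[f]] <- as.numeric(x)
      b <- if (!is.null(effects[[f]])) unname(effects[[f]][1]) else 0
      eta <- eta + b * x
      truth[f] <- b
      next
    }
    lv <- levs[[f]]
    x <- factor(sample(lv, n, replace = TRUE), levels = lv)
    out[[f]] <- x
    e <- stats::setNames(rep(0, length(lv)), lv)
    if (!is.null(effects[[f]])) e[names(effects[[f]])] <- effects[[f]]
    eta <- eta + e[as.character(x)]
    truth[paste0(f, lv[-1])] <- e[-1]
  }
  re <- stats::rnorm(n_dates, 0, random_sd)
  names(re) <- sprintf("d%03d", seq_len(n_dates))
  eta <- eta + re[as.character(out$date)]
  mu <- exp(eta)
  out$response <- if (family == "poisson") stats::rpois(n, mu) else
    stats::rnbinom(n, size = theta, mu = mu)
  attr(out, "truth") <- truth
  out
}
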