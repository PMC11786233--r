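# Doubly-weighted (IPW x IPCW) average treatment effect on the
# risk-difference scale, with symmetric propensity trimming, person-level
# bootstrap confidence intervals and negative-control diagnostics.
#
# For episode i with treatment T, observation indicator D (1 iff followed
# for the endpoint's full window), outcome Y (missing when D = 0),
# propensity e(X) and observation probability pi(X):
#   Horvitz-Thompson: mean(T D Y / (e pi)) - mean((1-T) D Y / ((1-e) pi))
#   Hajek:            each arm's weighted mean of Y with weights
#                     T D/(e pi) and (1-T) D/((1-e) pi)
# Unobserved episodes contribute zero weight; the Hajek form is the
# default for its variance stability.

#' Estimator configuration
#'
#' @param trim_bounds `c(low, high)` symmetric propensity trimming bounds;
#'   episodes with `low <= e(X) <= high` (closed interval) are kept.
#' @param estimator_form `"hajek"` (weight-normalized, default) or
#'   `"horvitz_thompson"`.
#' @param n_bootstrap bootstrap replicates.
#' @param bootstrap_unit `"person"` (episodes resampled with their person;
#'   the default, since episodes nest in patients) or `"episode"`.
#' @param refit_in_bootstrap refit the nuisance models (at fixed chosen
#'   hyperparameters) inside every replicate; trimming is likewise
#'   re-applied per replicate.
#' @param ci_level confidence level for the percentile interval.
#' @param seed integer seed for the resampling stream.
#' @return an object of class `estimator_config`.
#' @export
estimator_config <- function(trim_bounds = c(0.05, 0.95),
                             estimator_form = c("hajek", "horvitz_thompson"),
                             n_bootstrap = 1000L,
                             bootstrap_unit = c("person", "episode"),
                             refit_in_bootstrap = TRUE,
                             ci_level = 0.95,
                             seed = 1L) {
  estimator_form <- match.arg(estimator_form)
  bootstrap_unit <- match.arg(bootstrap_unit)
  stopifnot(length(trim_bounds) == 2, trim_bounds[1] > 0,
            trim_bounds[1] < trim_bounds[2], trim_bounds[2] < 1,
            n_bootstrap >= 2, ci_level > 0, ci_level < 1)
  structure(
    list(trim_bounds = trim_bounds, estimator_form = estimator_form,
         n_bootstrap = as.integer(n_bootstrap),
         bootstrap_unit = bootstrap_unit,
         refit_in_bootstrap = isTRUE(refit_in_bootstrap),
         ci_level = ci_level, seed = as.integer(seed)),
    class = "estimator_config"
  )
}

#' Symmetric propensity trimming
#'
#' @param scores propensity scores in (0, 1).
#' @param bounds `c(low, high)`; kept iff `low <= score <= high`.
#' @param t_ind optional treatment indicator, for per-arm retention counts.
#' @return integer indices of retained rows; attribute `"counts"` holds
#'   total/trimmed (and per-arm) counts.
#' @export
trim_propensity <- function(scores, bounds = c(0.05, 0.95), t_ind = NULL) {
  stopifnot(all(scores > 0), all(scores < 1))
  keep <- which(scores >= bounds[1] & scores <= bounds[2])
  if (!length(keep)) stop("trimming removed every episode")
  counts <- list(n_total = length(scores), n_trimmed = length(scores) -
                   length(keep))
  if (!is.null(t_ind)) {
    counts$kept_treated <- sum(t_ind[keep] == 1L)
    counts$kept_control <- sum(t_ind[keep] == 0L)
  }
  attr(keep, "counts") <- counts
  keep
}

#' Inverse-probability-weighted risk difference
#'
#' @param y binary outcome; may be `NA` exactly where `d = 0`.
#' @param t_ind treatment indicator (1 = first-line).
#' @param d observation indicator.
#' @param e propensity scores, clipped into (0, 1).
#' @param pi observation probabilities, clipped into (0, 1); pass 1 to
#'   switch censoring weighting off.
#' @param form `"hajek"` or `"horvitz_thompson"`.
#' @return the estimated risk difference (a single number).
#' @export
ate_estimate <- function(y, t_ind, d, e, pi = 1,
                         form = c("hajek", "horvitz_thompson")) {
  form <- match.arg(form)
  n <- length(y)
  if (length(pi) == 1L) pi <- rep(pi, n)
  stopifnot(length(t_ind) == n, length(d) == n, length(e) == n,
            length(pi) == n, all(e > 0 & e < 1), all(pi > 0 & pi <= 1))
  if (any(d == 1L & is.na(y))) stop("y must be present wherever d = 1")
  y0 <- ifelse(d == 1L, y, 0)          # D = 0 contributes zero
  w1 <- t_ind * d / (e * pi)
  w0 <- (1 - t_ind) * d / ((1 - e) * pi)
  if (sum(w1) == 0 || sum(w0) == 0) {
    stop("an arm has zero total weight; estimate undefined")
  }
  if (form == "horvitz_thompson") {
    mean(w1 * y0) - mean(w0 * y0)
  } else {
    sum(w1 * y0) / sum(w1) - sum(w0 * y0) / sum(w0)
  }
}

## ---- analysis problems ----------------------------------------------------

# Bundle everything the estimator and bootstrap need for one endpoint.
# Nuisance scores can be fixed vectors (refits disabled) or come from
# designs/fits that are refit per replicate:
#   - e_fit / pi_fit: nuisance_fit objects, refit at chosen hyperparameters
#   - x / x_obs: plain designs refit by unpenalized logistic regression
# The observation design defaults to [X, T, T*X], allowing disenrollment to
# differ by arm.

#' Assemble an estimation problem for one endpoint
#'
#' @param y,t_ind,d outcome, treatment and observation indicators.
#' @param person_id person identifier per episode (bootstrap clusters).
#' @param x propensity design matrix (used to (re)fit e by logistic
#'   regression when no `e_fit`/`e` is given).
#' @param e,pi optional fixed nuisance score vectors.
#' @param e_fit,pi_fit optional [select_and_fit()] results to refit inside
#'   the bootstrap.
#' @param x_obs observation-model design; defaults to `[x, t, t*x]`.
#' @return an `ipw_problem`.
#' @export
ipw_problem <- function(y, t_ind, d, person_id, x = NULL,
                        e = NULL, pi = NULL, e_fit = NULL, pi_fit = NULL,
                        x_obs = NULL) {
  n <- length(y)
  if (is.null(x_obs) && !is.null(x)) {
    xt <- x * t_ind
    colnames(xt) <- paste0("t_x_", colnames(x))
    x_obs <- cbind(x, t_ind = t_ind, xt)
  }
  # full-data logistic coefficients double as warm starts for the
  # per-replicate refits inside the bootstrap
  e_beta <- if (!is.null(x) && is.null(e_fit)) fit_logistic(x, t_ind)
  pi_beta <- if (!is.null(x_obs) && is.null(pi_fit) && any(d == 0L)) {
    fit_logistic(x_obs, d)
  }
  structure(
    list(y = y, t_ind = t_ind, d = d, person_id = person_id,
         x = x, x_obs = x_obs, e = e, pi = pi,
         e_fit = e_fit, pi_fit = pi_fit,
         e_beta = e_beta, pi_beta = pi_beta, n = n),
    class = "ipw_problem"
  )
}

# Nuisance scores for a row subset; refit when designs/fits are present.
# Returns NULL when a refit is impossible (degenerate resample).
problem_scores <- function(pb, rows, refit, seed = 1L) {
  e <- if (!refit || (is.null(pb$e_fit) && is.null(pb$x))) {
    if (is.null(pb$e)) stop("no propensity scores or design available")
    pb$e[rows]
  } else if (!is.null(pb$e_fit)) {
    refit_scores(pb$e_fit, pb$x[rows, , drop = FALSE], pb$t_ind[rows],
                 seed = seed)
  } else {
    if (length(unique(pb$t_ind[rows])) < 2L) return(NULL)
    xr <- pb$x[rows, , drop = FALSE]
    clip_prob(predict_logistic(
      fit_logistic(xr, pb$t_ind[rows], start = pb$e_beta), xr))
  }
  if (is.null(e)) return(NULL)
  pi <- if (all(pb$d[rows] == 1L)) {
    rep(1, length(rows))
  } else if (!refit || (is.null(pb$pi_fit) && is.null(pb$x_obs))) {
    if (is.null(pb$pi)) rep(1, length(rows)) else pb$pi[rows]
  } else if (!is.null(pb$pi_fit)) {
    refit_scores(pb$pi_fit, pb$x_obs[rows, , drop = FALSE], pb$d[rows],
                 seed = seed + 1L)
  } else {
    xr <- pb$x_obs[rows, , drop = FALSE]
    clip_prob(predict_logistic(
      fit_logistic(xr, pb$d[rows], start = pb$pi_beta), xr))
  }
  if (is.null(pi)) return(NULL)
  list(e = e, pi = pi)
}

point_estimate <- function(pb, config, rows = seq_len(pb$n),
                           refit = TRUE, seed = 1L) {
  sc <- problem_scores(pb, rows, refit = refit, seed = seed)
  if (is.null(sc)) return(NULL)
  keep <- trim_propensity(sc$e, config$trim_bounds, pb$t_ind[rows])
  i <- rows[keep]
  est <- ate_estimate(pb$y[i], pb$t_ind[i], pb$d[i],
                      sc$e[keep], sc$pi[keep], config$estimator_form)
  list(est = est, counts = attr(keep, "counts"),
       n_observed = sum(pb$d[i] == 1L))
}

#' Bootstrap confidence interval for the weighted risk difference
#'
#' Resamples the bootstrap unit (persons by default, carrying all their
#' episodes) with replacement; per replicate the nuisance models are
#' optionally refit at fixed hyperparameters, trimming is re-applied, and
#' the estimate recomputed. The interval is the percentile interval of the
#' replicate estimates; `significant` means the interval excludes the
#' risk-difference null of 0.
#'
#' @param problem an [ipw_problem()].
#' @param config an [estimator_config()].
#' @param endpoint,contrast labels carried into the result.
#' @return an `ate_result`: point estimate, `ci`, counts, the replicate
#'   `draws`, and `significant`.
#' @export
bootstrap_ate <- function(problem, config, endpoint = "endpoint",
                          contrast = "contrast") {
  pb <- problem
  pt <- point_estimate(pb, config, refit = config$refit_in_bootstrap,
                       seed = derive_seed(config$seed, "point"))
  if (is.null(pt)) stop("point estimate not computable")

  units <- if (config$bootstrap_unit == "person") {
    split(seq_len(pb$n), pb$person_id)
  } else {
    as.list(seq_len(pb$n))
  }
  nu <- length(units)
  set.seed(derive_seed(config$seed, "bootstrap"))
  draws <- rep(NA_real_, config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    rows <- unlist(units[sample.int(nu, nu, replace = TRUE)],
                   use.names = FALSE)
    res <- tryCatch(
      point_estimate(pb, config, rows = rows,
                     refit = config$refit_in_bootstrap, seed = b),
      error = function(e) NULL
    )
    if (!is.null(res)) draws[b] <- res$est
  }
  failed <- sum(is.na(draws))
  if (failed > 0.10 * config$n_bootstrap) {
    stop(failed, " of ", config$n_bootstrap,
         " bootstrap replicates failed (empty arm after trimming?)")
  }
  ok <- draws[!is.na(draws)]
  alpha <- 1 - config$ci_level
  ci <- unname(quantile(ok, c(alpha / 2, 1 - alpha / 2)))
  structure(
    list(endpoint = endpoint, contrast = contrast,
         ate = pt$est, ci = ci,
         n_total = pt$counts$n_total, n_trimmed = pt$counts$n_trimmed,
         n_observed = pt$n_observed,
         significant = ci[1] > 0 || ci[2] < 0,
         bootstrap_draws = draws, n_failed = failed),
    class = "ate_result"
  )
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf(
    "<ate_result> %s | %s\n  risk difference %+.4f (%.0f%% CI %+.4f to %+.4f)%s\n",
    x$contrast, x$endpoint, x$ate, 95, x$ci[1], x$ci[2],
    if (x$significant) " *" else ""))
  cat(sprintf("  n=%d (%d trimmed, %d observed)\n",
              x$n_total, x$n_trimmed, x$n_observed))
  invisible(x)
}

ate_result_row <- function(r) {
  data.table(
    contrast = r$contrast, endpoint = r$endpoint, ate = r$ate,
    ci_low = r$ci[1], ci_high = r$ci[2], n_total = r$n_total,
    n_trimmed = r$n_trimmed, n_observed = r$n_observed,
    significant = r$significant
  )
}

#' Negative-control outcome suite
#'
#' Runs the full trimmed, doubly-weighted estimator with bootstrap CIs on
#' each negative-control outcome at the 1-month and 3-month windows. Since
#' the controls are believed causally unrelated to the choice of
#' antibiotic, any interval excluding 0 flags residual bias.
#'
#' @param cohort a two-arm [contrast_cohort()].
#' @param features the propensity feature matrix for those episodes.
#' @param bundle the claims bundle.
#' @param config an [estimator_config()].
#' @param codes code lists naming the negative controls.
#' @param e optional fixed propensity scores (otherwise refit by logistic
#'   regression on `features` per replicate).
#' @return a data.table with one row per control x window and a `pass`
#'   flag (`TRUE` iff the CI contains 0).
#' @export
negative_control_suite <- function(cohort, features, bundle,
                                   config = estimator_config(),
                                   codes = default_codes(), e = NULL) {
  co <- as.data.table(cohort)
  specs <- Filter(function(s) s$family == "negative_control",
                  default_endpoints(codes))
  x <- fm_matrix(features)
  rows <- lapply(specs, function(spec) {
    lab <- label_outcome(co, bundle, spec)
    pb <- ipw_problem(lab$Y, co$T_ind, lab$D, co$person_id, x = x, e = e)
    r <- bootstrap_ate(pb, config, endpoint = spec$name,
                       contrast = "negative_control")
    out <- ate_result_row(r)
    out$window_days <- spec$window_days
    out$pass <- !r$significant
    out
  })
  rbindlist(rows)
}
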