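# End-to-end analysis of one treatment contrast: cohort -> confounders ->
# outcome labels -> nuisance models -> trimmed doubly-weighted estimates
# with bootstrap CIs -> negative-control diagnostics.

#' Run a full treatment contrast
#'
#' @param bundle a [claims_bundle][simulate_claims()] (simulated or read
#'   from disk).
#' @param contrast `"first_line_vs_fluoroquinolone"` or
#'   `"first_line_vs_beta_lactam"`.
#' @param endpoints list of [endpoint_spec()]s to estimate; default: the
#'   failure and adverse-event endpoints from [default_endpoints()]
#'   (negative controls are handled separately below).
#' @param cohort_cfg a [cohort_config()].
#' @param est_cfg an [estimator_config()]; its seed drives all randomness.
#' @param nuisance `"logistic"` fits both nuisance models by unpenalized
#'   logistic regression (fast, refit per bootstrap replicate);
#'   `"selected"` runs the full split/grid-search/CV-AUROC selection over
#'   the three learner families.
#' @param grid hyperparameter grids for `nuisance = "selected"`.
#' @param feature_set `"expert"` or `"auto"`.
#' @param min_prevalence prevalence floor for automatic features.
#' @param ipcw set `FALSE` to force the observation probability to 1
#'   (diagnostic: quantifies what censoring weighting corrects).
#' @param negative_controls also run the negative-control suite.
#' @return a `contrast_report`: attrition table, per-endpoint results
#'   (estimate, CI, counts, significance), naive unadjusted differences,
#'   nuisance-model summaries, negative-control table, and provenance.
#' @export
run_contrast <- function(bundle,
                         contrast = c("first_line_vs_fluoroquinolone",
                                      "first_line_vs_beta_lactam"),
                         endpoints = NULL,
                         cohort_cfg = cohort_config(),
                         est_cfg = estimator_config(),
                         nuisance = c("logistic", "selected"),
                         grid = default_grid(),
                         feature_set = c("expert", "auto"),
                         min_prevalence = 0.01,
                         ipcw = TRUE,
                         negative_controls = TRUE) {
  contrast <- match.arg(contrast)
  nuisance <- match.arg(nuisance)
  feature_set <- match.arg(feature_set)
  codes <- cohort_cfg$codes
  if (is.null(endpoints)) {
    endpoints <- Filter(function(s) s$family != "negative_control",
                        default_endpoints(codes))
  }

  cohort <- build_cohort(bundle, cohort_cfg)
  attrition <- attrition_report(cohort)
  comparator <- sub("^first_line_vs_", "", contrast)
  cc <- contrast_cohort(cohort, comparator)

  fm <- if (feature_set == "expert") {
    build_expert_features(cc, bundle, cohort_cfg)
  } else {
    build_auto_features(cc, bundle, min_prevalence = min_prevalence)
  }
  x <- fm_matrix(fm)

  ## propensity model
  e_fit <- NULL
  e_scores <- NULL
  nuisance_info <- list(mode = nuisance)
  if (nuisance == "selected") {
    plan <- make_splits(cc, seed = est_cfg$seed)
    e_fit <- select_and_fit(fm, cc$T_ind, plan, grid, target = "treatment")
    e_scores <- e_fit$scores
    nuisance_info$treatment <- list(
      chosen_family = e_fit$chosen_family,
      hyperparameters = e_fit$hyperparameters,
      cv_auroc = as.list(e_fit$cv_auroc)
    )
  } else {
    e_scores <- clip_prob(predict_logistic(fit_logistic(x, cc$T_ind), x))
    nuisance_info$treatment <- list(chosen_family = "logistic",
                                    auroc = auc_mw(e_scores, cc$T_ind))
  }

  labels <- label_outcomes(cc, bundle, endpoints)

  ## observation model per distinct follow-up window (selected mode)
  pi_fits <- list()
  if (nuisance == "selected") {
    wins <- unique(vapply(endpoints, `[[`, 0L, "window_days"))
    for (w in wins) {
      ep_w <- Filter(function(s) s$window_days == w, endpoints)[[1]]
      d_w <- labels[[paste0("D_", ep_w$name)]]
      if (length(unique(d_w)) < 2L) next
      xt <- x * cc$T_ind
      colnames(xt) <- paste0("t_x_", colnames(x))
      x_obs <- cbind(x, t_ind = cc$T_ind, xt)
      pi_fits[[as.character(w)]] <- select_and_fit(
        x_obs, d_w, make_splits(cc, seed = est_cfg$seed + w), grid,
        target = "observation")
    }
  }

  results <- list()
  naive <- list()
  pi_cache <- list()  # point observation scores per window (logistic mode)
  for (spec in endpoints) {
    D <- labels[[paste0("D_", spec$name)]]
    Y <- labels[[paste0("Y_", spec$name)]]
    pi_fit <- pi_fits[[as.character(spec$window_days)]]
    wkey <- as.character(spec$window_days)
    if (ipcw && nuisance == "logistic" && is.null(pi_cache[[wkey]]) &&
        length(unique(D)) > 1L) {
      xt <- x * cc$T_ind
      colnames(xt) <- paste0("t_x_", colnames(x))
      x_obs <- cbind(x, t_ind = cc$T_ind, xt)
      pi_cache[[wkey]] <- clip_prob(predict_logistic(
        fit_logistic(x_obs, D), x_obs))
    }
    pb <- ipw_problem(
      Y, cc$T_ind, D, cc$person_id,
      x = if (nuisance == "logistic") x else NULL,
      e = e_scores,
      pi = if (!ipcw) rep(1, nrow(cc)) else
        if (!is.null(pi_fit)) pi_fit$scores else pi_cache[[wkey]],
      e_fit = e_fit,
      pi_fit = if (ipcw) pi_fit else NULL
    )
    if (!ipcw) { pb$x_obs <- NULL; pb$pi_fit <- NULL }
    r <- tryCatch(
      bootstrap_ate(pb, est_cfg, endpoint = spec$name, contrast = contrast),
      error = function(e) {
        stop("endpoint '", spec$name, "': ", conditionMessage(e),
             call. = FALSE)
      })
    results[[spec$name]] <- ate_result_row(r)
    obs1 <- D == 1L & cc$T_ind == 1L
    obs0 <- D == 1L & cc$T_ind == 0L
    naive[[spec$name]] <- data.table(
      endpoint = spec$name,
      naive_rd = mean(Y[obs1]) - mean(Y[obs0]),
      p_treated = mean(cc$T_ind), p_observed = mean(D)
    )
  }

  nc_table <- NULL
  if (negative_controls) {
    nc_cfg <- est_cfg
    nc_table <- negative_control_suite(
      cc, fm, bundle, nc_cfg, codes,
      e = if (nuisance == "selected") e_scores else NULL)
  }

  structure(
    list(
      contrast = contrast,
      attrition = attrition,
      results = rbindlist(results),
      naive = rbindlist(naive),
      nuisance = nuisance_info,
      negative_controls = nc_table,
      n_eligible = nrow(cc),
      feature_report = feature_report(fm),
      seed = est_cfg$seed
    ),
    class = "contrast_report"
  )
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("<contrast_report>", x$contrast, "-", x$n_eligible,
      "eligible episodes\n")
  print(x$results)
  if (!is.null(x$negative_controls)) {
    cat("negative controls passing:", sum(x$negative_controls$pass), "/",
        nrow(x$negative_controls), "\n")
  }
  invisible(x)
}

#' Forest plot of contrast results
#'
#' @param report a [run_contrast()] report.
#' @return a ggplot object (requires the `ggplot2` package).
#' @export
plot_forest <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_forest() requires the 'ggplot2' package")
  }
  res <- report$results
  res$endpoint <- factor(res$endpoint, levels = rev(res$endpoint))
  ggplot2::ggplot(res, ggplot2::aes(x = 100 * .data$ate,
                                    y = .data$endpoint)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = 100 * .data$ci_low, xmax = 100 * .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Adjusted risk difference (percentage points)",
                  y = NULL, title = report$contrast) +
    ggplot2::theme_minimal()
}
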