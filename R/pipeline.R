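# Orchestration: YAML-configured end-to-end runs, deterministic outputs,
# and a validation harness that re-derives the estimator's operating
# characteristics from simulation. These functions are the programmatic
# surface behind the thin command-line wrapper in `inst/cli/uticausal.R`.

sim_config_from_list <- function(lst) {
  lst <- lst %||% list()
  args <- lst[intersect(names(lst), names(formals(sim_config)))]
  for (nm in c("comorbidity_rates", "treatment_model", "baseline_risk_model",
               "censoring_model", "exclusion_injection_rates")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(sim_config, args)
}

cohort_config_from_list <- function(lst) {
  lst <- lst %||% list()
  args <- lst[intersect(names(lst), names(formals(cohort_config)))]
  for (nm in c("recurrent_window_1", "recurrent_window_2")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(cohort_config, args)
}

estimator_config_from_list <- function(lst) {
  lst <- lst %||% list()
  args <- lst[intersect(names(lst), names(formals(estimator_config)))]
  if (!is.null(args$trim_bounds)) args$trim_bounds <- unlist(args$trim_bounds)
  do.call(estimator_config, args)
}

#' Simulate a claims bundle and write it to disk
#'
#' @param config a [sim_config()], a list of its arguments, or the path of
#'   a YAML file holding them.
#' @param out output directory for the bundle tables and manifest.
#' @param format `"csv"` or `"parquet"`.
#' @param seed optional override of the config's seed.
#' @return the bundle manifest, invisibly.
#' @export
cmd_simulate <- function(config, out, format = "csv", seed = NULL) {
  cfg <- if (inherits(config, "sim_config")) {
    config
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    sim_config_from_list(yaml::read_yaml(config))
  } else {
    sim_config_from_list(config)
  }
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
  }
  bundle <- simulate_claims(cfg)
  manifest <- write_bundle(bundle, out, format = format)
  message("wrote ", length(manifest$tables), " tables to ", out,
          " (seed ", cfg$seed, ")")
  invisible(manifest)
}

#' Run the full analysis pipeline and write its reports
#'
#' Reads (or takes) a bundle, runs [run_contrast()] under the supplied
#' config, and writes `attrition.csv`, `results.csv`, `naive.csv`,
#' `negative_controls.csv`, `feature_report.csv`, `nuisance.json` and a
#' `provenance.json` carrying the config hash and seed. Outputs are
#' deterministic given config + seed; existing outputs are not overwritten
#' unless `force = TRUE`.
#'
#' @param bundle a `claims_bundle` or the directory of a written bundle.
#' @param config a list (or YAML path) with optional sections `contrast`,
#'   `cohort`, `estimator`, `endpoints` (names from [default_endpoints()]),
#'   `nuisance`, `feature_set`, `ipcw`, `negative_controls`.
#' @param out output directory.
#' @param seed optional override of the estimator seed.
#' @param force overwrite existing outputs.
#' @return the [run_contrast()] report, invisibly.
#' @export
cmd_run <- function(bundle, config = list(), out, seed = NULL,
                    force = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.character(bundle)) bundle <- read_bundle(bundle)

  est_cfg <- estimator_config_from_list(config$estimator)
  if (!is.null(seed)) est_cfg$seed <- as.integer(seed)
  cohort_cfg <- cohort_config_from_list(config$cohort)
  endpoints <- NULL
  if (!is.null(config$endpoints)) {
    all_eps <- default_endpoints(cohort_cfg$codes)
    missing <- setdiff(unlist(config$endpoints), names(all_eps))
    if (length(missing)) stop("unknown endpoint(s): ",
                              paste(missing, collapse = ", "))
    endpoints <- all_eps[unlist(config$endpoints)]
  }

  out_files <- c("attrition.csv", "results.csv", "naive.csv",
                 "negative_controls.csv", "feature_report.csv",
                 "nuisance.json", "provenance.json")
  if (!force && dir.exists(out) &&
      any(file.exists(file.path(out, out_files)))) {
    stop("output files already exist in ", out, "; use force = TRUE")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  report <- run_contrast(
    bundle,
    contrast = config$contrast %||% "first_line_vs_fluoroquinolone",
    endpoints = endpoints,
    cohort_cfg = cohort_cfg,
    est_cfg = est_cfg,
    nuisance = config$nuisance %||% "logistic",
    feature_set = config$feature_set %||% "expert",
    ipcw = config$ipcw %||% TRUE,
    negative_controls = config$negative_controls %||% TRUE
  )

  fwrite(report$attrition, file.path(out, "attrition.csv"))
  fwrite(report$results, file.path(out, "results.csv"))
  fwrite(report$naive, file.path(out, "naive.csv"))
  if (!is.null(report$negative_controls)) {
    fwrite(report$negative_controls, file.path(out, "negative_controls.csv"))
  }
  fwrite(report$feature_report, file.path(out, "feature_report.csv"))
  jsonlite::write_json(report$nuisance, file.path(out, "nuisance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = config_hash(list(config, est_cfg$seed)),
         seed = est_cfg$seed, contrast = report$contrast,
         n_eligible = report$n_eligible,
         package_version = as.character(utils::packageVersion("uticausal"))),
    file.path(out, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Simulation-study validation of the estimator
#'
#' Re-derives the estimator's operating characteristics from synthetic
#' bundles with known truth: (1) confounding correction — the adjusted
#' estimate recovers the true risk difference where the naive contrast is
#' biased; (2) censoring correction — with informative disenrollment the
#' doubly-weighted estimator stays unbiased while dropping the censoring
#' weights leaves bias; (3) negative controls — all control outcomes are
#' compatible with zero effect. Thresholds and problem sizes sit in
#' `profile` and default to a scale that runs in a couple of minutes.
#'
#' @param profile named list: `n_persons`, `delta`, `seeds` (vector),
#'   `adjusted_tol`, `naive_min_bias`, `ipcw_tol`, `noipcw_min_bias`,
#'   `n_bootstrap`, `force_null_pi` (plant a misspecified observation
#'   model to demonstrate the check fires).
#' @param out optional directory for a `validation.csv` report.
#' @return data.table of `(check, value, threshold, pass)`; attribute
#'   `"all_pass"` summarizes it.
#' @export
cmd_validate <- function(profile = list(), out = NULL) {
  pr <- modifyList(list(
    n_persons = 20000L, delta = -0.02, seeds = c(11L, 12L),
    adjusted_tol = 0.0075, naive_min_bias = 0.015,
    ipcw_tol = 0.0075, noipcw_min_bias = 0.01,
    n_bootstrap = 200L, force_null_pi = FALSE
  ), profile)
  checks <- list()
  add <- function(check, value, threshold, pass) {
    checks[[length(checks) + 1L]] <<- data.table(
      check = check, value = value, threshold = threshold, pass = pass)
  }

  ## confounding correction
  est <- naive <- truth <- numeric(0)
  for (s in pr$seeds) {
    r <- estimate_on_simulated(
      sim_config_confounded(pr$n_persons, pr$delta, seed = s),
      n_bootstrap = 0L)
    est <- c(est, r$adjusted); naive <- c(naive, r$naive)
    truth <- c(truth, r$true_ate)
  }
  add("adjusted_bias_confounded", mean(est - truth), pr$adjusted_tol,
      abs(mean(est - truth)) <= pr$adjusted_tol)
  add("naive_bias_confounded", mean(naive - truth), pr$naive_min_bias,
      abs(mean(naive - truth)) >= pr$naive_min_bias)

  ## censoring correction
  est <- est_nopi <- truth <- cens <- numeric(0)
  for (s in pr$seeds) {
    r <- estimate_on_simulated(
      sim_config_censored(pr$n_persons, pr$delta, seed = s),
      n_bootstrap = 0L, ipcw = !pr$force_null_pi)
    r2 <- estimate_on_simulated(
      sim_config_censored(pr$n_persons, pr$delta, seed = s),
      n_bootstrap = 0L, ipcw = FALSE)
    est <- c(est, r$adjusted); est_nopi <- c(est_nopi, r2$adjusted)
    truth <- c(truth, r$true_ate); cens <- c(cens, 1 - r$p_observed)
  }
  add("censored_fraction", mean(cens), 0.2, mean(cens) >= 0.2)
  add("ipcw_bias", mean(est - truth), pr$ipcw_tol,
      abs(mean(est - truth)) <= pr$ipcw_tol)
  add("no_ipcw_bias", mean(est_nopi - truth), pr$noipcw_min_bias,
      abs(mean(est_nopi - truth)) >= pr$noipcw_min_bias)

  ## negative controls
  if (pr$n_bootstrap >= 50L) {
    cfg <- sim_config_confounded(max(4000L, pr$n_persons %/% 5L), pr$delta,
                                 seed = pr$seeds[1])
    bundle <- simulate_claims(cfg)
    cohort <- build_cohort(bundle)
    cc <- contrast_cohort(cohort)
    fm <- build_expert_features(cc, bundle)
    nc <- negative_control_suite(
      cc, fm, bundle,
      estimator_config(n_bootstrap = pr$n_bootstrap, seed = pr$seeds[1]))
    add("negative_controls_passing", sum(nc$pass), nrow(nc) - 1,
        sum(nc$pass) >= nrow(nc) - 1)
  } else {
    warning("n_bootstrap < 50: negative-control coverage check skipped")
  }

  res <- rbindlist(checks)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    fwrite(res, file.path(out, "validation.csv"))
  }
  setattr(res, "all_pass", all(res$pass))
  res
}

#' Simulate, analyze, and compare against the simulator's truth
#'
#' Helper used by validation and acceptance studies: simulates a bundle,
#' runs the cohort/feature/outcome/nuisance/estimation chain on the
#' composite-failure endpoint with logistic nuisance models, and returns
#' the adjusted estimate next to the naive contrast and the true effect.
#'
#' @param cfg a [sim_config()].
#' @param n_bootstrap bootstrap replicates (0 skips the CI).
#' @param ipcw set `FALSE` to drop censoring weighting.
#' @param estimator_form passed to [estimator_config()].
#' @param design `"expert"` uses the full expert feature matrix;
#'   `"compact"` collapses the chronic-condition window indicators to a
#'   comorbidity count (still spanning the simulator's structural models),
#'   which keeps repeated-simulation studies with nuisance refits in every
#'   bootstrap replicate fast.
#' @return a list: `adjusted`, `naive`, `true_ate`, `p_observed`, `ci`
#'   (when bootstrapped), `n_eligible`.
#' @export
estimate_on_simulated <- function(cfg, n_bootstrap = 0L, ipcw = TRUE,
                                  estimator_form = "hajek",
                                  design = c("expert", "compact")) {
  design <- match.arg(design)
  bundle <- simulate_claims(cfg)
  cohort <- build_cohort(bundle)
  cc <- contrast_cohort(cohort, cfg$comparator_class)
  fm <- build_expert_features(cc, bundle)
  x <- fm_matrix(fm)
  if (design == "compact") {
    meta <- attr(fm, "feature_meta")
    com_cols <- meta$column[meta$source == "expert" &
                              meta$window %in% c("0_6m", "6_12m", "12_24m") &
                              !startsWith(meta$column, "abx_")]
    spec_cols <- grep("^specialty_", colnames(x), value = TRUE)
    x <- cbind(
      age = x[, "age"], year_frac = x[, "year_frac"],
      comorbid = rowSums(x[, com_cols, drop = FALSE]),
      x[, spec_cols, drop = FALSE],
      uti_past_year = x[, "uti_past_year"]
    )
  }
  spec <- default_endpoints()$composite_failure
  lab <- label_outcome(cc, bundle, spec)

  e <- clip_prob(predict_logistic(fit_logistic(x, cc$T_ind), x))
  pi <- rep(1, nrow(cc))
  if (ipcw && any(lab$D == 0L)) {
    xt <- x * cc$T_ind
    colnames(xt) <- paste0("t_x_", colnames(x))
    x_obs <- cbind(x, t_ind = cc$T_ind, xt)
    pi <- clip_prob(predict_logistic(fit_logistic(x_obs, lab$D), x_obs))
  }
  est_cfg <- estimator_config(
    n_bootstrap = max(2L, n_bootstrap), estimator_form = estimator_form,
    seed = cfg$seed)
  keep <- trim_propensity(e, est_cfg$trim_bounds, cc$T_ind)
  adjusted <- ate_estimate(lab$Y[keep], cc$T_ind[keep], lab$D[keep],
                           e[keep], pi[keep], est_cfg$estimator_form)
  obs1 <- lab$D == 1L & cc$T_ind == 1L
  obs0 <- lab$D == 1L & cc$T_ind == 0L
  out <- list(
    adjusted = adjusted,
    naive = mean(lab$Y[obs1]) - mean(lab$Y[obs0]),
    true_ate = true_ate(bundle),
    p_observed = mean(lab$D),
    n_eligible = nrow(cc)
  )
  if (n_bootstrap > 0L) {
    pb <- ipw_problem(lab$Y, cc$T_ind, lab$D, cc$person_id, x = x,
                      e = e, pi = pi)
    if (!ipcw) pb$x_obs <- NULL
    r <- bootstrap_ate(pb, est_cfg, endpoint = spec$name)
    out$ci <- r$ci
    out$significant <- r$significant
  }
  out
}
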