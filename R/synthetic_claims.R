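# Synthetic OMOP-shaped claims with a known causal structure.
#
# The generator encodes a structural causal model at the episode level:
# confounders (age, calendar time, chronic-comorbidity burden, provider
# specialty, prior UTI) drive treatment assignment through a logit,
# the control-arm outcome risk through a second logit, and per-month
# disenrollment through a hazard logit that may additionally depend on the
# assigned treatment. The treatment acts additively on the risk scale, so
# the marginal average treatment effect equals the configured risk
# difference whenever clamping to [0,1] never binds. Potential outcomes are
# drawn with a shared uniform per episode and stored in a hidden truth
# table, giving every downstream stage an exact oracle.

#' Configuration for the synthetic-claims generator
#'
#' Defaults describe the data regime the pipeline targets: a female-majority
#' adult claims population (mean age 51.7, SD 20.1 years), UTI episodes
#' spread over a 10-year study window, chronic-comorbidity histories over the
#' 24 months before the index date, antibiotic dispensings within days of
#' diagnosis, and treatment assignment correlated with age, calendar year,
#' comorbidity burden and specialty so that recipients of the comparator
#' classes are older and sicker (confounding by indication).
#'
#' Coefficient vectors act on the standardized episode covariates
#' `(intercept, age, year, comorbid, specialty, prior_uti)` where `age` is
#' `(age - 52)/20`, `year` is scaled to `[-1, 1]` across the range of
#' admissible index dates, `comorbid` is the chronic-condition count,
#' `specialty` is an internal-medicine indicator and `prior_uti` a
#' prior-year UTI indicator. Coefficient names may be any subset of these
#' terms; omitted terms are 0. The censoring model additionally accepts
#' `treat`, `treat_age` and `treat_comorbid`, allowing disenrollment to
#' differ by arm (without arm-dependent censoring, dropping the censoring
#' weights leaves the risk difference unbiased, so these terms are what
#' makes censoring weighting demonstrably necessary).
#'
#' @param n_persons number of persons (one index UTI episode each).
#' @param prop_female fraction of female persons; males trigger the
#'   complicated-UTI exclusion downstream.
#' @param age_distribution `c(mean, sd)` in years, truncated to `[18, 95]`
#'   (injection rules may lower ages below 18).
#' @param comorbidity_rates named baseline prevalences for the chronic
#'   conditions in [default_codes()]; realized prevalence rises with age.
#' @param treatment_model named coefficients for the first-line assignment
#'   logit.
#' @param baseline_risk_model named coefficients for the control-arm
#'   composite-failure risk logit.
#' @param true_risk_difference additive treatment effect (risk difference)
#'   of first-line treatment on composite failure, in `[-1, 1]`.
#' @param censoring_model named coefficients for the per-30-day
#'   disenrollment hazard logit; the default intercept of -20 produces no
#'   censoring.
#' @param exclusion_injection_rates named fractions of episodes given
#'   records that trigger each exclusion rule; names among `underage`,
#'   `washout`, `multi_drug`, `off_list`, `no_treatment`, `recurrent`,
#'   `complicated`, `pregnancy`.
#' @param comparator_class the non-first-line arm: `"fluoroquinolone"` or
#'   `"beta_lactam"`.
#' @param prior_uti_rate fraction of episodes with a single UTI diagnosis
#'   200-360 days before index.
#' @param history_antibiotic_rate fraction of persons with an innocuous
#'   prior antibiotic dispensing 30-720 days before index (well outside the
#'   washout window); feeds the prior-exposure expert features.
#' @param negative_control_effect additive rate shift on negative-control
#'   outcomes for treated episodes; keep 0 except to plant a bias signal
#'   for diagnostics testing.
#' @param study_window `c(start, end)` ISO dates of the claims window.
#' @param seed integer; identical seed + config give byte-identical tables.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_persons = 500, seed = 1)
#' bundle <- simulate_claims(cfg)
#' true_ate(bundle)
sim_config <- function(n_persons = 10000,
                       prop_female = 0.9,
                       age_distribution = c(51.7, 20.1),
                       comorbidity_rates = c(
                         hypertension = 0.36, diabetes = 0.14,
                         arthritis = 0.20, cancer = 0.10,
                         chronic_kidney_disease = 0.05, autoimmune = 0.05,
                         thyroid_disorder = 0.01
                       ),
                       treatment_model = c(
                         intercept = 0.45, age = -0.9, year = 0.7,
                         comorbid = -0.25, specialty = -0.5, prior_uti = -0.2
                       ),
                       baseline_risk_model = c(
                         intercept = -2.2, age = 0.8, year = 0,
                         comorbid = 0.22, specialty = 0.15, prior_uti = 0.35
                       ),
                       true_risk_difference = -0.02,
                       censoring_model = c(intercept = -20),
                       exclusion_injection_rates = c(
                         underage = 0, washout = 0, multi_drug = 0,
                         off_list = 0, no_treatment = 0, recurrent = 0,
                         complicated = 0, pregnancy = 0
                       ),
                       comparator_class = c("fluoroquinolone", "beta_lactam"),
                       prior_uti_rate = 0.10,
                       history_antibiotic_rate = 0.15,
                       negative_control_effect = 0,
                       study_window = c("2012-01-01", "2021-12-31"),
                       seed = 1L) {
  comparator_class <- match.arg(comparator_class)
  full_rates <- c(
    underage = 0, washout = 0, multi_drug = 0, off_list = 0,
    no_treatment = 0, recurrent = 0, complicated = 0, pregnancy = 0
  )
  if (length(exclusion_injection_rates)) {
    bad <- setdiff(names(exclusion_injection_rates), names(full_rates))
    if (length(bad)) stop("unknown exclusion rule(s): ", paste(bad, collapse = ", "))
    full_rates[names(exclusion_injection_rates)] <- exclusion_injection_rates
  }
  cfg <- list(
    n_persons = as.integer(n_persons),
    prop_female = prop_female,
    age_distribution = age_distribution,
    comorbidity_rates = comorbidity_rates,
    treatment_model = treatment_model,
    baseline_risk_model = baseline_risk_model,
    true_risk_difference = true_risk_difference,
    censoring_model = censoring_model,
    exclusion_injection_rates = full_rates,
    comparator_class = comparator_class,
    prior_uti_rate = prior_uti_rate,
    history_antibiotic_rate = history_antibiotic_rate,
    negative_control_effect = negative_control_effect,
    study_window = study_window,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_persons > 0,
    cfg$prop_female >= 0, cfg$prop_female <= 1,
    length(cfg$age_distribution) == 2, cfg$age_distribution[2] > 0,
    all(cfg$comorbidity_rates >= 0), all(cfg$comorbidity_rates <= 1),
    abs(cfg$true_risk_difference) <= 1,
    all(cfg$exclusion_injection_rates >= 0),
    all(cfg$exclusion_injection_rates <= 1)
  )
  base_terms <- c("intercept", "age", "year", "comorbid", "specialty",
                  "prior_uti")
  cens_terms <- c(base_terms, "treat", "treat_age", "treat_comorbid")
  for (m in c("treatment_model", "baseline_risk_model")) {
    bad <- setdiff(names(cfg[[m]]), base_terms)
    if (length(bad)) {
      stop(m, " has unknown coefficient name(s): ",
           paste(bad, collapse = ", "))
    }
  }
  bad <- setdiff(names(cfg$censoring_model), cens_terms)
  if (length(bad)) {
    stop("censoring_model has unknown coefficient name(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# expand a partial named coefficient vector to the full term set, filling
# omitted terms with 0
fill_coefs <- function(coefs, terms) {
  full <- setNames(numeric(length(terms)), terms)
  full[names(coefs)] <- coefs
  full
}

#' Preset simulation configurations for validation studies
#'
#' `sim_config_confounded()` pairs confounding by indication with a nonzero
#' risk difference so the naive arm contrast is biased by several percentage
#' points while the adjusted estimator is not; coefficients are kept
#' moderate so propensities stay well inside (0, 1) (treatment positivity)
#' and inverse-probability weights remain stable. `sim_config_censored()`
#' adds informative, arm-dependent disenrollment (roughly a quarter of
#' episodes lose 30-day follow-up, differentially by age across arms) on
#' top of the same confounding, again with hazards bounded away from 1 so
#' the observation probability never collapses.
#'
#' @param n_persons,true_risk_difference,seed,... passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_confounded <- function(n_persons = 50000,
                                  true_risk_difference = -0.02,
                                  seed = 1L, ...) {
  sim_config(
    n_persons = n_persons,
    treatment_model = c(
      intercept = 0.3, age = -0.5, year = 0.4, comorbid = -0.15,
      specialty = -0.25, prior_uti = -0.12
    ),
    baseline_risk_model = c(
      intercept = -2.1, age = 0.9, year = 0, comorbid = 0.25,
      specialty = 0.15, prior_uti = 0.35
    ),
    true_risk_difference = true_risk_difference,
    seed = seed,
    ...
  )
}

#' @rdname sim_config_confounded
#' @export
sim_config_censored <- function(n_persons = 50000,
                                true_risk_difference = -0.02,
                                seed = 1L, ...) {
  # hazards stay inside roughly [0.07, 0.85], so the observation
  # probability never collapses toward 0 (censoring positivity) while the
  # treated arm censors much more steeply with age than the control arm
  sim_config_confounded(
    n_persons = n_persons,
    true_risk_difference = true_risk_difference,
    censoring_model = c(
      intercept = -1.15, age = -0.2, comorbid = 0.1,
      treat = 0.1, treat_age = 0.6, treat_comorbid = 0.1
    ),
    seed = seed,
    ...
  )
}

# Standardize the raw covariates used by all three structural models.
sim_covariates <- function(age, year_frac, year_span, n_comorbid,
                           spec_internal, prior_uti) {
  cbind(
    intercept = 1,
    age = (age - 52) / 20,
    year = 2 * (year_frac - year_span[1]) / (year_span[2] - year_span[1]) - 1,
    comorbid = n_comorbid,
    specialty = as.numeric(spec_internal),
    prior_uti = as.numeric(prior_uti)
  )
}

#' Simulate an OMOP-shaped claims bundle
#'
#' Draws persons, chronic-condition histories, one index UTI episode per
#' person, treatment dispensings, outcomes, adverse events, negative-control
#' events and enrollment spans from the structural model in the config, and
#' lays them out as the seven claims tables. Dates are integer day offsets
#' from the study window start; [write_bundle()] renders them as ISO dates.
#'
#' A hidden `truth` table records both potential outcomes, their
#' probabilities, the true propensity and the true per-window observation
#' probabilities for every index episode, which is what makes the simulator
#' usable as an oracle.
#'
#' @param config a [sim_config()].
#' @return an object of class `claims_bundle`: a list of data.tables
#'   `person`, `condition_occurrence`, `drug_exposure`, `visit_occurrence`,
#'   `measurement`, `observation_period`, `truth`, plus `meta`.
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  study_start <- as.Date(cfg$study_window[1])
  total_days <- as.integer(as.Date(cfg$study_window[2]) - study_start)
  if (total_days < 1000) stop("study window must span at least 1000 days")
  n <- cfg$n_persons
  rates <- cfg$exclusion_injection_rates

  ## ---- persons -----------------------------------------------------------
  sex <- ifelse(runif(n) < cfg$prop_female, "F", "M")
  age <- pmin(pmax(rnorm(n, cfg$age_distribution[1], cfg$age_distribution[2]),
                   18), 95)
  inj <- lapply(rates, function(r) runif(n) < r)
  age[inj$underage] <- runif(sum(inj$underage), 12, 17.5)

  ## ---- index episodes ----------------------------------------------------
  lo <- 730L
  hi <- total_days - 120L
  index_day <- lo + floor(runif(n) * (hi - lo + 1))
  year_frac <- index_day / 365.25
  year_span <- c(lo, hi) / 365.25
  birth_year <- as.integer(format(study_start, "%Y")) +
    as.integer(floor(year_frac)) - as.integer(round(age))

  ## chronic comorbidities: prevalence rises with age; one record per
  ## present condition at a uniform lag in the 24-month lookback
  com_names <- names(cfg$comorbidity_rates)
  com_present <- matrix(FALSE, n, length(com_names),
                        dimnames = list(NULL, com_names))
  for (j in seq_along(com_names)) {
    p <- plogis(qlogis(cfg$comorbidity_rates[j]) + 0.035 * (age - 52))
    com_present[, j] <- runif(n) < p
  }
  n_comorbid <- rowSums(com_present)

  specialty_levels <- c("family_medicine", "internal_medicine",
                        "emergency", "obgyn", "urology", "other")
  specialty <- sample(specialty_levels, n, replace = TRUE,
                      prob = c(0.31, 0.14, 0.08, 0.05, 0.03, 0.39))
  prior_uti <- runif(n) < cfg$prior_uti_rate

  X <- sim_covariates(age, year_frac, year_span, n_comorbid,
                      specialty == "internal_medicine", prior_uti)

  ## ---- treatment ---------------------------------------------------------
  tm <- fill_coefs(cfg$treatment_model, colnames(X))
  e_true <- plogis(drop(X %*% tm))
  T_ind <- as.integer(runif(n) < e_true)

  ## ---- potential outcomes (shared-uniform coupling) ----------------------
  delta <- cfg$true_risk_difference
  p0 <- plogis(drop(X %*% fill_coefs(cfg$baseline_risk_model, colnames(X))))
  p1_raw <- p0 + delta
  clamped <- p1_raw < 0 | p1_raw > 1
  if (mean(clamped) > 0.01) {
    stop("clamping would alter ", round(100 * mean(clamped), 1),
         "% of outcome probabilities; the configured risk difference is ",
         "not identifiable as a marginal effect")
  }
  p1 <- pmin(pmax(p1_raw, 0), 1)
  U <- runif(n)
  Y0 <- as.integer(U < p0)
  Y1 <- as.integer(U < p1)
  Y_obs <- ifelse(T_ind == 1L, Y1, Y0)

  ## ---- censoring ---------------------------------------------------------
  Xc <- cbind(X, treat = T_ind, treat_age = T_ind * X[, "age"],
              treat_comorbid = T_ind * n_comorbid)
  cm <- fill_coefs(cfg$censoring_model, colnames(Xc))
  haz <- plogis(drop(Xc %*% cm))
  # geometric months-until-disenrollment by inverse CDF, capped at the
  # study horizon so vanishing hazards cannot overflow
  haz_c <- pmin(pmax(haz, 1e-8), 1 - 1e-8)
  months_enrolled <- pmin(floor(log(runif(n)) / log1p(-haz_c)),
                          ceiling(total_days / 30) + 1)
  enroll_end <- pmin(index_day + 30L * as.integer(months_enrolled) +
                       floor(runif(n) * 30), total_days)
  enroll_start <- pmax(index_day - 730L - floor(runif(n) * 365), 0L)
  pi30 <- (1 - haz)
  pi90 <- (1 - haz)^3

  person_id <- seq_len(n)
  episode_id <- sprintf("p%d_e1", person_id)

  ## ---- event tables ------------------------------------------------------
  codes <- default_codes()
  cond <- list()
  drug <- list()
  visits <- list()
  meas <- list()

  # index diagnosis + visit
  cond$index <- data.table(
    person_id = person_id, concept_code = "C-UTI",
    date = index_day, visit_context = "outpatient"
  )
  visits$index <- data.table(
    person_id = person_id, visit_date = index_day,
    visit_type = "outpatient", provider_specialty = specialty
  )

  # comorbidity history: one record per present condition, lag 1..720 days
  ij <- which(com_present, arr.ind = TRUE)
  if (nrow(ij)) {
    com_codes <- unlist(codes$comorbidities)[com_names]
    cond$comorbid <- data.table(
      person_id = person_id[ij[, 1]],
      concept_code = unname(com_codes[ij[, 2]]),
      date = index_day[ij[, 1]] - (1L + floor(runif(nrow(ij)) * 720)),
      visit_context = "outpatient"
    )
  }

  # prior-year UTI
  if (any(prior_uti)) {
    w <- which(prior_uti)
    cond$prior_uti <- data.table(
      person_id = person_id[w], concept_code = "C-UTI",
      date = index_day[w] - (200L + floor(runif(length(w)) * 161)),
      visit_context = "outpatient"
    )
  }

  # menopause history for a fraction of older women
  meno <- sex == "F" & age > 50 & runif(n) < 0.12
  if (any(meno)) {
    w <- which(meno)
    cond$menopause <- data.table(
      person_id = person_id[w], concept_code = codes$menopause[1],
      date = index_day[w] - (100L + floor(runif(length(w)) * 600)),
      visit_context = "outpatient"
    )
  }

  # treatment dispensing 0-2 days after index
  abx <- codes$antibiotic_classes
  t_class <- ifelse(T_ind == 1L, "first_line", cfg$comparator_class)
  t_code <- character(n)
  fl <- which(t_class == "first_line")
  cp <- which(t_class != "first_line")
  t_code[fl] <- sample(abx$first_line, length(fl), replace = TRUE)
  t_code[cp] <- sample(abx[[cfg$comparator_class]], length(cp), replace = TRUE)
  # dispensed on the index day: keeps treatment ascertainment independent
  # of how soon afterwards a person disenrolls
  rx_day <- index_day
  keep_rx <- !inj$no_treatment
  # off-list injection swaps the dispensing for a non-covered antibiotic
  t_code[inj$off_list] <- "D-FLUCON"
  t_class[inj$off_list] <- "off_list"
  drug$index <- data.table(
    person_id = person_id[keep_rx], concept_code = t_code[keep_rx],
    drug_class = t_class[keep_rx], start_date = rx_day[keep_rx],
    days_supply = sample(c(5L, 7L, 10L), sum(keep_rx), replace = TRUE)
  )

  # washout violation: an antibiotic 3 days before index
  if (any(inj$washout)) {
    w <- which(inj$washout)
    drug$washout <- data.table(
      person_id = person_id[w],
      concept_code = sample(unlist(abx), length(w), replace = TRUE),
      drug_class = "injected_washout", start_date = index_day[w] - 3L,
      days_supply = 7L
    )
  }

  # multi-drug violation: a second class 4 days after index
  if (any(inj$multi_drug)) {
    w <- which(inj$multi_drug & keep_rx)
    if (length(w)) {
      other <- ifelse(t_class[w] == "first_line",
                      cfg$comparator_class, "first_line")
      code2 <- vapply(other, function(cl) sample(abx[[cl]], 1), "")
      drug$multi <- data.table(
        person_id = person_id[w], concept_code = unname(code2),
        drug_class = unname(other), start_date = index_day[w] + 4L,
        days_supply = 7L
      )
    }
  }

  # innocuous prior antibiotic history (well outside the washout window)
  hist_abx <- runif(n) < cfg$history_antibiotic_rate
  if (any(hist_abx)) {
    w <- which(hist_abx)
    cls <- sample(names(abx), length(w), replace = TRUE)
    drug$history <- data.table(
      person_id = person_id[w],
      concept_code = vapply(cls, function(cl) sample(abx[[cl]], 1), ""),
      drug_class = cls,
      start_date = index_day[w] - (30L + floor(runif(length(w)) * 691)),
      days_supply = 7L
    )
  }

  # recurrent pattern: two extra outpatient UTI diagnoses inside 180 days
  if (any(inj$recurrent)) {
    w <- which(inj$recurrent)
    cond$recurrent <- data.table(
      person_id = rep(person_id[w], 2L), concept_code = "C-UTI",
      date = c(index_day[w] - 120L, index_day[w] - 50L),
      visit_context = "outpatient"
    )
  }

  # complicated UTI: acute code within 180d or long-term comorbidity earlier
  if (any(inj$complicated)) {
    w <- which(inj$complicated)
    acute <- runif(length(w)) < 0.5
    cond$complicated <- data.table(
      person_id = person_id[w],
      concept_code = ifelse(
        acute,
        sample(codes$complicated_acute, length(w), replace = TRUE),
        sample(codes$complicated_longterm, length(w), replace = TRUE)
      ),
      date = index_day[w] - ifelse(acute,
                                   10L + floor(runif(length(w)) * 161),
                                   400L + floor(runif(length(w)) * 301)),
      visit_context = "outpatient"
    )
  }

  # pregnancy within 280 days before index
  if (any(inj$pregnancy)) {
    w <- which(inj$pregnancy)
    cond$pregnancy <- data.table(
      person_id = person_id[w], concept_code = codes$pregnancy[1],
      date = index_day[w] - (1L + floor(runif(length(w)) * 270)),
      visit_context = "outpatient"
    )
  }

  # observed composite-failure revisit: subtype + visit context drawn,
  # recorded only while the person is still enrolled
  ev <- which(Y_obs == 1L)
  if (length(ev)) {
    ev_day <- index_day[ev] + 1L + floor(runif(length(ev)) * 30)
    ev_code <- sample(c("C-UTI", "C-PYELO", "C-SEPSIS"), length(ev),
                      replace = TRUE, prob = c(0.70, 0.20, 0.10))
    ev_ctx <- sample(c("outpatient", "inpatient"), length(ev),
                     replace = TRUE, prob = c(0.85, 0.15))
    keep <- ev_day <= enroll_end[ev]
    cond$failure <- data.table(
      person_id = person_id[ev][keep], concept_code = ev_code[keep],
      date = ev_day[keep], visit_context = ev_ctx[keep]
    )
    visits$failure <- data.table(
      person_id = person_id[ev][keep], visit_date = ev_day[keep],
      visit_type = ev_ctx[keep],
      provider_specialty = sample(specialty_levels, sum(keep),
                                  replace = TRUE)
    )
  }

  # adverse events, independent of treatment and covariates
  ae_spec <- list(
    diarrhea = c(rate = 0.04, win = 15),
    acute_kidney_injury = c(rate = 0.02, win = 30),
    dermatologic = c(rate = 0.02, win = 30),
    c_difficile = c(rate = 0.01, win = 90)
  )
  for (ae in names(ae_spec)) {
    hit <- which(runif(n) < ae_spec[[ae]]["rate"])
    if (!length(hit)) next
    d <- index_day[hit] + 1L + floor(runif(length(hit)) * ae_spec[[ae]]["win"])
    keep <- d <= enroll_end[hit]
    cond[[ae]] <- data.table(
      person_id = person_id[hit][keep],
      concept_code = codes$adverse_events[[ae]][1],
      date = d[keep], visit_context = "outpatient"
    )
  }

  # negative controls: independent of treatment unless an effect is planted
  nc_rate <- 0.03
  for (nc in names(codes$negative_controls)) {
    p_nc <- nc_rate + cfg$negative_control_effect * T_ind
    hit <- which(runif(n) < pmin(pmax(p_nc, 0), 1))
    if (!length(hit)) next
    d <- index_day[hit] + 1L + floor(runif(length(hit)) * 90)
    keep <- d <= enroll_end[hit]
    cond[[nc]] <- data.table(
      person_id = person_id[hit][keep],
      concept_code = codes$negative_controls[[nc]][1],
      date = d[keep], visit_context = "outpatient"
    )
  }

  # laboratory measurements ordered at presentation
  ua <- which(runif(n) < 0.24)
  bl <- which(runif(n) < 0.04)
  meas$ua <- data.table(person_id = person_id[ua],
                        measurement_type = "urinalysis", date = index_day[ua])
  meas$bl <- data.table(person_id = person_id[bl],
                        measurement_type = "blood", date = index_day[bl])

  ## ---- assemble ----------------------------------------------------------
  condition_occurrence <- rbindlist(cond, use.names = TRUE)
  drug_exposure <- rbindlist(drug, use.names = TRUE)
  visit_occurrence <- rbindlist(visits, use.names = TRUE)
  measurement <- rbindlist(meas, use.names = TRUE)
  observation_period <- data.table(
    person_id = person_id, enroll_start = enroll_start,
    enroll_end = enroll_end
  )
  # enforce: no event outside the person's enrollment span
  span <- observation_period
  clip_to_span <- function(tab, datecol) {
    m <- span[tab, on = "person_id"]
    tab[m[[datecol]] >= m$enroll_start & m[[datecol]] <= m$enroll_end]
  }
  condition_occurrence <- clip_to_span(condition_occurrence, "date")
  drug_exposure <- clip_to_span(drug_exposure, "start_date")
  visit_occurrence <- clip_to_span(visit_occurrence, "visit_date")
  measurement <- clip_to_span(measurement, "date")
  setorder(condition_occurrence, person_id, date, concept_code)
  setorder(drug_exposure, person_id, start_date, concept_code)
  setorder(visit_occurrence, person_id, visit_date, visit_type)
  setorder(measurement, person_id, date, measurement_type)

  person <- data.table(person_id = person_id, sex = sex,
                       birth_year = birth_year)

  expected_eligible <- sex == "F" & !Reduce(`|`, inj)
  truth <- data.table(
    episode_id = episode_id, person_id = person_id, index_date = index_day,
    T_true = T_ind, treatment_class = t_class,
    p0 = p0, p1 = p1, Y0 = Y0, Y1 = Y1,
    e_true = e_true, pi30_true = pi30, pi90_true = pi90,
    hazard = haz, expected_eligible = expected_eligible
  )

  structure(
    list(
      person = person,
      condition_occurrence = condition_occurrence,
      drug_exposure = drug_exposure,
      visit_occurrence = visit_occurrence,
      measurement = measurement,
      observation_period = observation_period,
      truth = truth,
      meta = list(
        config = cfg, study_start = study_start, total_days = total_days,
        simulated = TRUE
      )
    ),
    class = "claims_bundle"
  )
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>", nrow(x$person), "persons,",
      nrow(x$condition_occurrence), "condition records,",
      nrow(x$drug_exposure), "dispensings\n")
  cat("  study window:", format(x$meta$study_start), "+",
      x$meta$total_days, "days;",
      if (!is.null(x$truth)) "truth table present" else "no truth table",
      "\n")
  invisible(x)
}

#' Ground-truth average treatment effect of a simulated bundle
#'
#' The mean of `Y(1) - Y(0)` over the episodes the simulator expected to be
#' eligible. Equals the configured risk difference exactly in expectation
#' whenever clamping of outcome probabilities never binds.
#'
#' @param bundle a simulated [claims_bundle][simulate_claims()].
#' @return a single number, the true risk difference.
#' @export
true_ate <- function(bundle) {
  if (is.null(bundle$truth)) {
    stop("bundle has no truth table; true_ate() requires simulated data")
  }
  tr <- bundle$truth[bundle$truth$expected_eligible == TRUE]
  mean(tr$Y1 - tr$Y0)
}
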