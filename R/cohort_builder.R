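# Episode identification and the inclusion/exclusion cascade.
#
# Exclusions are flags, never row deletions: every identified episode stays
# in the cohort with its full flag set, which makes eligibility independent
# of rule order and lets the attrition report attribute removals in a fixed,
# documented sequence.

#' Cohort-construction configuration
#'
#' @param codes a code-list config shaped like [default_codes()].
#' @param treatment_window_days dispensings from the index day through this
#'   many days after it count as the episode's treatment.
#' @param washout_days any dispensing in the `washout_days` days strictly
#'   before the index day excludes the episode (prior antibiotic exposure).
#' @param recurrent_window_1 `c(count, days)`: first recurrence clause,
#'   "at least `count` episodes in the last `days` days".
#' @param recurrent_window_2 `c(count, days)`: second recurrence clause.
#' @param recurrent_rule `"and"` combines the clauses conjunctively (as the
#'   definition is usually printed), `"or"` disjunctively (the common
#'   clinical convention). A warning notes the ambiguity at build time when
#'   the default is in force.
#' @param complicated_lookback_days lookback for acute complicating
#'   procedures/diagnoses; long-term complicating comorbidities have
#'   unlimited lookback.
#' @param pregnancy_lookback_days lookback for pregnancy codes.
#' @param min_age_years minimum age at the index date.
#' @param episode_gap_days diagnoses closer together than or equal to this
#'   gap collapse into one episode.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(codes = default_codes(),
                          treatment_window_days = 7L,
                          washout_days = 7L,
                          recurrent_window_1 = c(count = 2L, days = 180L),
                          recurrent_window_2 = c(count = 3L, days = 365L),
                          recurrent_rule = c("and", "or"),
                          complicated_lookback_days = 180L,
                          pregnancy_lookback_days = 280L,
                          min_age_years = 18L,
                          episode_gap_days = 30L) {
  recurrent_rule <- match.arg(recurrent_rule)
  validate_codes(codes)
  stopifnot(
    treatment_window_days > 0, washout_days > 0,
    recurrent_window_1[["days"]] > 0, recurrent_window_2[["days"]] > 0,
    complicated_lookback_days > 0, episode_gap_days > 0
  )
  structure(
    list(
      codes = codes,
      treatment_window_days = as.integer(treatment_window_days),
      washout_days = as.integer(washout_days),
      recurrent_window_1 = recurrent_window_1,
      recurrent_window_2 = recurrent_window_2,
      recurrent_rule = recurrent_rule,
      complicated_lookback_days = as.integer(complicated_lookback_days),
      pregnancy_lookback_days = as.integer(pregnancy_lookback_days),
      min_age_years = as.integer(min_age_years),
      episode_gap_days = as.integer(episode_gap_days)
    ),
    class = "cohort_config"
  )
}

exclusion_rules <- function() {
  c("male", "underage", "pregnancy", "washout", "recurrent",
    "complicated", "no_treatment", "multi_drug", "off_list")
}

#' Identify UTI episodes from outpatient diagnosis claims
#'
#' Outpatient UTI diagnosis codes are clustered per person: consecutive
#' diagnoses no more than `episode_gap_days` apart belong to one episode,
#' whose index date is the earliest diagnosis in the cluster. Demographic
#' exclusion flags (male sex, under-age at index) are attached here; all
#' other flags start `FALSE` and are set by the later cascade stages.
#'
#' @param bundle a [claims_bundle][simulate_claims()].
#' @param config a [cohort_config()].
#' @return an `episode_cohort`: a data.table with one row per episode
#'   (`episode_id`, `person_id`, `index_date`, `age_at_index`, `sex`,
#'   `treatment_class`, `T_ind`, the `excl_*` flag columns, `eligible`).
#' @export
identify_episodes <- function(bundle, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!length(config$codes$uti)) stop("empty UTI code list")
  cond <- as.data.table(bundle$condition_occurrence)
  if (!nrow(cond)) stop("condition table is empty")
  dx <- cond[concept_code %in% config$codes$uti &
               visit_context == "outpatient",
             .(person_id, date)]
  if (!nrow(dx)) stop("no outpatient UTI diagnoses found")
  setorder(dx, person_id, date)
  gap <- config$episode_gap_days
  dx[, cluster_id := {
    d <- date
    cumsum(c(1L, as.integer(diff(d) > gap)))
  }, by = person_id]
  ep <- dx[, .(index_date = min(date)), by = .(person_id, cluster_id)]
  ep[, episode_id := paste0("p", person_id, "_e", cluster_id)]
  ep[, cluster_id := NULL]

  person <- as.data.table(bundle$person)
  ep <- person[, .(person_id, sex, birth_year)][ep, on = "person_id"]
  start_year <- as.integer(format(bundle$meta$study_start, "%Y"))
  ep[, age_at_index := start_year + as.integer(floor(index_date / 365.25)) -
       birth_year]
  ep[, treatment_class := NA_character_]
  ep[, T_ind := NA_integer_]
  for (r in exclusion_rules()) set(ep, j = paste0("excl_", r), value = FALSE)
  ep[, excl_male := sex == "M"]
  ep[, excl_underage := age_at_index < config$min_age_years]
  ep[, eligible := FALSE]
  setorder(ep, person_id, index_date)
  setcolorder(ep, c("episode_id", "person_id", "index_date", "age_at_index",
                    "sex", "birth_year", "treatment_class", "T_ind"))
  structure(ep, class = c("episode_cohort", class(ep)),
            stages_done = "identify")
}

#' Assign the treatment class and treatment-related exclusion flags
#'
#' The episode's treatment is the unique antibiotic class dispensed from
#' the index day through `treatment_window_days` after it. Episodes with
#' dispensings from more than one covered class are flagged `multi_drug`;
#' episodes whose only dispensing is outside the covered classes are
#' flagged `off_list` (as is any episode with an off-list dispensing in the
#' window); episodes with no dispensing at all are flagged `no_treatment`.
#' Any dispensing in the `washout_days` days strictly before the index day
#' flags `washout`.
#'
#' @param cohort an [episode_cohort][identify_episodes()].
#' @param bundle the claims bundle.
#' @param config a [cohort_config()].
#' @return the cohort with treatment columns and flags filled in.
#' @export
assign_treatment <- function(cohort, bundle, config) {
  drug <- as.data.table(bundle$drug_exposure)
  cls_map <- rbindlist(lapply(
    names(config$codes$antibiotic_classes),
    function(cl) data.table(concept_code = config$codes$antibiotic_classes[[cl]],
                            class = cl)
  ))
  co <- as.data.table(cohort)
  key <- co[, .(episode_id, person_id, index_date)]

  rx <- drug[key, on = "person_id", allow.cartesian = TRUE]
  rx[, offset := start_date - index_date]
  win <- rx[offset >= 0L & offset <= config$treatment_window_days]
  win <- cls_map[win, on = "concept_code"]

  per_ep <- win[, .(
    n_classes = uniqueN(stats::na.omit(class)),
    the_class = if (uniqueN(stats::na.omit(class)) == 1L)
      stats::na.omit(class)[1] else NA_character_,
    any_off_list = anyNA(class),
    any_rx = .N > 0L
  ), by = episode_id]

  wash <- rx[offset >= -config$washout_days & offset <= -1L,
             .(washout = .N > 0L), by = episode_id]

  co[, `:=`(treatment_class = NA_character_, T_ind = NA_integer_,
            excl_no_treatment = TRUE, excl_multi_drug = FALSE,
            excl_off_list = FALSE, excl_washout = FALSE)]
  co[per_ep, on = "episode_id", `:=`(
    excl_no_treatment = FALSE,
    excl_multi_drug = i.n_classes > 1L,
    excl_off_list = i.any_off_list,
    treatment_class = ifelse(i.n_classes == 1L & !i.any_off_list,
                             i.the_class, NA_character_)
  )]
  co[wash, on = "episode_id", excl_washout := i.washout]
  co[, T_ind := ifelse(is.na(treatment_class), NA_integer_,
                       as.integer(treatment_class == "first_line"))]
  keep_attrs(co, cohort, stage = "treatment")
}

#' Flag recurrent-UTI episodes
#'
#' An episode is recurrent when the person's episode count inside sliding
#' windows ending at (and including) the index date meets the configured
#' clauses — by default at least 2 episodes in 180 days AND at least 3 in
#' 365 days; set `recurrent_rule = "or"` for the disjunctive convention.
#'
#' @inheritParams assign_treatment
#' @return the cohort with `excl_recurrent` filled in.
#' @export
flag_recurrent <- function(cohort, config) {
  co <- as.data.table(cohort)
  if (config$recurrent_rule == "and") {
    warning("recurrent rule 'and' (as printed in common definitions) is in ",
            "force; clinical convention is often 'or' - set recurrent_rule ",
            "explicitly to silence", call. = FALSE)
  }
  w1 <- config$recurrent_window_1
  w2 <- config$recurrent_window_2
  setorder(co, person_id, index_date)
  co[, `:=`(n_prior_180 = 1L, n_prior_365 = 1L)]
  # window counts only matter for persons with >1 episode
  multi <- co[, .N, by = person_id][N > 1L, person_id]
  if (length(multi)) {
    co[person_id %in% multi, `:=`(
      n_prior_180 = {
        i <- seq_len(.N)
        i - findInterval(index_date - w1[["days"]], index_date)
      },
      n_prior_365 = {
        i <- seq_len(.N)
        i - findInterval(index_date - w2[["days"]], index_date)
      }
    ), by = person_id]
  }
  c1 <- co$n_prior_180 >= w1[["count"]]
  c2 <- co$n_prior_365 >= w2[["count"]]
  co[, excl_recurrent := if (config$recurrent_rule == "and") c1 & c2 else c1 | c2]
  co[, c("n_prior_180", "n_prior_365") := NULL]
  keep_attrs(co, cohort, stage = "recurrent")
}

#' Flag complicated-UTI episodes
#'
#' Sets `excl_complicated` when an acute complicating procedure/diagnosis
#' occurs within `complicated_lookback_days` up to the index date, or a
#' long-term complicating comorbidity (e.g. neurogenic bladder,
#' genitourinary cancer) occurs at any time up to the index date. Male sex
#' always counts as complicated (`excl_male` is set at identification).
#' Pregnancy codes within `pregnancy_lookback_days` set `excl_pregnancy`.
#'
#' @inheritParams assign_treatment
#' @return the cohort with `excl_complicated` and `excl_pregnancy` filled.
#' @export
flag_complicated <- function(cohort, bundle, config) {
  co <- as.data.table(cohort)
  cond <- as.data.table(bundle$condition_occurrence)
  key <- co[, .(episode_id, person_id, index_date)]

  hits <- function(code_list, min_lag, max_lag) {
    ev <- cond[concept_code %in% code_list]
    if (!nrow(ev)) return(character())
    m <- ev[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
    m[, lag_days := index_date - date]
    unique(m[lag_days >= min_lag & (is.infinite(max_lag) | lag_days <= max_lag),
             episode_id])
  }

  acute <- hits(config$codes$complicated_acute, 0L,
                config$complicated_lookback_days)
  longterm <- hits(config$codes$complicated_longterm, 0L, Inf)
  preg <- hits(config$codes$pregnancy, 0L, config$pregnancy_lookback_days)

  co[, excl_complicated := episode_id %in% c(acute, longterm) | sex == "M"]
  co[, excl_pregnancy := episode_id %in% preg]
  keep_attrs(co, cohort, stage = "complicated")
}

#' Run the full inclusion/exclusion cascade
#'
#' Convenience wrapper: identify episodes, assign treatment, flag recurrent
#' and complicated episodes, then mark `eligible` for rows with no
#' exclusion flag and an assigned treatment class.
#'
#' @inheritParams identify_episodes
#' @param quiet suppress the recurrent-rule convention warning.
#' @return a fully flagged `episode_cohort`.
#' @export
build_cohort <- function(bundle, config = cohort_config(), quiet = TRUE) {
  co <- identify_episodes(bundle, config)
  co <- assign_treatment(co, bundle, config)
  co <- if (quiet) suppressWarnings(flag_recurrent(co, config))
        else flag_recurrent(co, config)
  co <- flag_complicated(co, bundle, config)
  finalize_eligibility(co)
}

#' @rdname build_cohort
#' @param cohort a flagged cohort.
#' @export
finalize_eligibility <- function(cohort) {
  co <- as.data.table(cohort)
  flag_cols <- paste0("excl_", exclusion_rules())
  any_flag <- Reduce(`|`, lapply(flag_cols, function(cn) co[[cn]]))
  co[, eligible := !any_flag & !is.na(treatment_class)]
  keep_attrs(co, cohort, stage = "final")
}

keep_attrs <- function(new, old, stage) {
  setattr(new, "class", unique(c("episode_cohort", class(new))))
  setattr(new, "stages_done", c(attr(old, "stages_done"), stage))
  new
}

#' Attrition report in flow-diagram order
#'
#' Applies the exclusion rules sequentially in the fixed documented order
#' (male, under-age, pregnancy, washout, recurrent, complicated,
#' no-treatment, multi-drug, off-list) and counts episodes removed at each
#' step. The order only affects attribution: the final eligible set is the
#' same for any ordering because flags are computed independently.
#'
#' @param cohort a fully flagged [episode_cohort][build_cohort()].
#' @return a data.table of `(rule, episodes_removed, episodes_remaining)`,
#'   starting from an `initial` row.
#' @export
attrition_report <- function(cohort) {
  co <- as.data.table(cohort)
  remaining <- rep(TRUE, nrow(co))
  rows <- list(data.table(rule = "initial", episodes_removed = 0L,
                          episodes_remaining = nrow(co)))
  for (r in exclusion_rules()) {
    flag <- co[[paste0("excl_", r)]]
    removed <- remaining & flag
    remaining <- remaining & !flag
    rows[[length(rows) + 1L]] <- data.table(
      rule = r, episodes_removed = sum(removed),
      episodes_remaining = sum(remaining)
    )
  }
  out <- rbindlist(rows)
  stopifnot(out$episodes_remaining[nrow(out)] == sum(co$eligible))
  out
}

#' Restrict a cohort to a two-arm contrast
#'
#' Keeps eligible episodes treated with first-line antibiotics or the named
#' comparator class and defines `T_ind = 1` for first-line.
#'
#' @param cohort a finalized cohort.
#' @param comparator `"fluoroquinolone"` or `"beta_lactam"`.
#' @return a data.table of eligible episodes in the two arms.
#' @export
contrast_cohort <- function(cohort,
                            comparator = c("fluoroquinolone", "beta_lactam")) {
  comparator <- match.arg(comparator)
  co <- as.data.table(cohort)
  out <- co[eligible & treatment_class %in% c("first_line", comparator)]
  if (!nrow(out[treatment_class == comparator])) {
    stop("comparator arm '", comparator, "' is empty after exclusions")
  }
  if (!nrow(out[treatment_class == "first_line"])) {
    stop("first-line arm is empty after exclusions")
  }
  out[, T_ind := as.integer(treatment_class == "first_line")]
  out
}
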