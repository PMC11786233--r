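# Confounder construction: expert features and automatic time-windowed
# features over the claims history.
#
# All history windows are computed in days with month = 30 days:
# (0,180], (180,360], (360,720] days before the index date, which partition
# the 24-month lookback. Lags are strictly positive, so nothing on or after
# the index day leaks into a history window; the at_index feature set is
# restricted to index-day records (labs ordered at presentation, provider
# specialty, calendar time).

feature_windows <- function() {
  list(`0_6m` = c(1L, 180L), `6_12m` = c(181L, 360L), `12_24m` = c(361L, 720L))
}

window_of_lag <- function(lag_days) {
  w <- feature_windows()
  out <- rep(NA_character_, length(lag_days))
  for (nm in names(w)) {
    out[lag_days >= w[[nm]][1] & lag_days <= w[[nm]][2]] <- nm
  }
  out
}

new_feature_matrix <- function(dt, meta) {
  setDF(dt)
  structure(dt, feature_meta = meta,
            class = c("feature_matrix", "data.frame"))
}

fm_meta <- function(fm) attr(fm, "feature_meta")

#' Numeric design matrix of a feature matrix
#'
#' @param fm a `feature_matrix` (a plain numeric matrix passes through).
#' @return a numeric matrix without the `episode_id` column.
#' @export
fm_matrix <- function(fm) {
  if (is.matrix(fm)) return(fm)
  cols <- setdiff(names(fm), "episode_id")
  m <- as.matrix(as.data.frame(fm)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- fm$episode_id
  m
}

# binary episode x concept-window indicators from an event table; when
# `all_concepts` is given the full concept x window grid is emitted with
# zero-filled columns for event-free combinations
windowed_indicators <- function(events, key, prefix, concept_col = "concept_code",
                                date_col = "date", all_concepts = NULL) {
  expected <- if (!is.null(all_concepts)) {
    as.vector(outer(paste0(prefix, all_concepts), names(feature_windows()),
                    paste, sep = "_"))
  }
  out <- key[, .(episode_id)]
  if (nrow(events)) {
    ev <- events[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
    ev[, lag_days := index_date - get(date_col)]
    ev[, window := window_of_lag(lag_days)]
    ev <- ev[!is.na(window)]
    if (nrow(ev)) {
      ev[, col_name := paste0(prefix, get(concept_col), "_", window)]
      wide <- dcast(ev, episode_id ~ col_name, fun.aggregate = length,
                    value.var = "window")
      num_cols <- setdiff(names(wide), "episode_id")
      for (cn in num_cols) {
        set(wide, j = cn, value = as.numeric(wide[[cn]] > 0))
      }
      out <- wide[out, on = "episode_id"]
      for (cn in num_cols) set(out, which(is.na(out[[cn]])), cn, 0)
    }
  }
  for (cn in setdiff(expected, names(out))) set(out, j = cn, value = 0)
  out
}

#' Build the domain-expert confounder set
#'
#' One binary column per configured concept group and time window
#' (conditions and prior antibiotic exposures by class over the
#' nonoverlapping 0-6, 6-12 and 12-24 month windows), plus the static and
#' index-day features: age, continuous calendar time and calendar-year
#' bins, provider specialty one-hots, urinalysis/blood tests ordered at
#' presentation, a menopause history flag, and a UTI-in-the-past-year flag.
#'
#' @param cohort episode rows to featurize (typically a
#'   [contrast_cohort()]).
#' @param bundle the claims bundle.
#' @param config a [cohort_config()] supplying the code lists.
#' @param groups condition groups to include; must name entries of
#'   `config$codes$comorbidities`.
#' @return a `feature_matrix` (data.frame with an `episode_id` column and a
#'   `feature_meta` attribute tagging each column's source and window).
#' @export
build_expert_features <- function(cohort, bundle, config = cohort_config(),
                                  groups = names(config$codes$comorbidities)) {
  co <- as.data.table(cohort)
  unknown <- setdiff(groups, names(config$codes$comorbidities))
  if (length(unknown)) {
    stop("unknown concept group(s): ", paste(unknown, collapse = ", "))
  }
  key <- co[, .(episode_id, person_id, index_date)]
  cond <- as.data.table(bundle$condition_occurrence)
  drug <- as.data.table(bundle$drug_exposure)
  meas <- as.data.table(bundle$measurement)
  visits <- as.data.table(bundle$visit_occurrence)
  start_year <- as.integer(format(bundle$meta$study_start, "%Y"))

  out <- co[, .(episode_id)]
  meta <- list()
  add_meta <- function(cols, source, concept, window) {
    if (length(cols)) {
      meta[[length(meta) + 1L]] <<- data.table(
        column = cols, source = source, concept = concept, window = window)
    }
  }

  ## demographics & calendar time
  out[, age := co$age_at_index]
  out[, year_frac := start_year + co$index_date / 365.25]
  add_meta(c("age", "year_frac"), "expert", c("age", "year"), "static")
  year <- start_year + floor(co$index_date / 365.25)
  for (bin in list(c(2012, 2014), c(2015, 2017), c(2018, 2021))) {
    cn <- sprintf("year_%d_%d", bin[1], bin[2])
    out[[cn]] <- as.numeric(year >= bin[1] & year <= bin[2])
    add_meta(cn, "expert", "year", "at_index")
  }

  ## condition groups x windows (full grid, zero-filled)
  grp_map <- rbindlist(lapply(groups, function(g) data.table(
    concept_code = config$codes$comorbidities[[g]], group = g)))
  grp_ev <- grp_map[cond, on = "concept_code", nomatch = NULL]
  wi <- windowed_indicators(grp_ev, key, prefix = "", concept_col = "group",
                            all_concepts = groups)
  newc <- setdiff(names(wi), "episode_id")
  out <- wi[out, on = "episode_id"]
  add_meta(newc, "expert", sub("_(0_6m|6_12m|12_24m)$", "", newc),
           sub("^.*_(0_6m|6_12m|12_24m)$", "\\1", newc))

  ## prior antibiotic exposure by class x windows (full grid, zero-filled)
  cls_map <- rbindlist(lapply(
    names(config$codes$antibiotic_classes),
    function(cl) data.table(
      concept_code = config$codes$antibiotic_classes[[cl]],
      abx = paste0("abx_", cl))))
  abx_ev <- cls_map[drug, on = "concept_code", nomatch = NULL]
  wi <- windowed_indicators(abx_ev, key, prefix = "", concept_col = "abx",
                            date_col = "start_date",
                            all_concepts = paste0(
                              "abx_", names(config$codes$antibiotic_classes)))
  newc <- setdiff(names(wi), "episode_id")
  out <- wi[out, on = "episode_id"]
  add_meta(newc, "expert", sub("_(0_6m|6_12m|12_24m)$", "", newc),
           sub("^.*_(0_6m|6_12m|12_24m)$", "\\1", newc))

  ## UTI history in the past year (strictly before index)
  uti_ev <- cond[concept_code %in% config$codes$uti &
                   visit_context == "outpatient"]
  m <- uti_ev[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
  m[, lag_days := index_date - date]
  hit <- unique(m[lag_days >= 1L & lag_days <= 365L, episode_id])
  out[, uti_past_year := as.numeric(episode_id %in% hit)]
  add_meta("uti_past_year", "expert", "uti_history", "static")

  ## menopause history (any time before or at index)
  men <- cond[concept_code %in% config$codes$menopause]
  m <- men[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
  hit <- unique(m[date <= index_date, episode_id])
  out[, menopause := as.numeric(episode_id %in% hit)]
  add_meta("menopause", "expert", "menopause", "static")

  ## labs ordered at presentation
  for (mt in c("urinalysis", "blood")) {
    mm <- meas[measurement_type == mt][key, on = "person_id",
                                       allow.cartesian = TRUE, nomatch = NULL]
    hit <- unique(mm[date == index_date, episode_id])
    cn <- paste0(mt, "_at_index")
    out[[cn]] <- as.numeric(out$episode_id %in% hit)
    add_meta(cn, "expert", mt, "at_index")
  }

  ## provider specialty at the index visit
  iv <- visits[key, on = c("person_id", visit_date = "index_date"),
               nomatch = NULL, mult = "first"]
  spec <- setNames(iv$provider_specialty, iv$episode_id)
  specialty <- unname(spec[out$episode_id])
  specialty[is.na(specialty)] <- "unknown"
  for (s in sort(unique(specialty))) {
    cn <- paste0("specialty_", s)
    out[[cn]] <- as.numeric(specialty == s)
    add_meta(cn, "expert", "specialty", "at_index")
  }

  setcolorder(out, "episode_id")
  out <- out[co[, .(episode_id)], on = "episode_id"]  # preserve row order
  new_feature_matrix(out, rbindlist(meta))
}

#' Build automatic time-windowed features from the raw vocabulary
#'
#' One binary column per concept code observed in the bundle (conditions,
#' dispensed drugs, and provider specialties) and per history window, kept
#' when its prevalence among the cohort's episodes reaches
#' `min_prevalence`. The vocabulary is derived from the data, never
#' hardcoded, which is what lets the same mechanism scale from a toy
#' vocabulary to a full claims coding system.
#'
#' @inheritParams build_expert_features
#' @param windows named list of `c(min_lag, max_lag)` day ranges; defaults
#'   to the three nonoverlapping 0-6, 6-12 and 12-24 month windows.
#' @param min_prevalence drop columns rarer than this fraction.
#' @return a `feature_matrix`.
#' @export
build_auto_features <- function(cohort, bundle, windows = feature_windows(),
                                min_prevalence = 0.01) {
  co <- as.data.table(cohort)
  key <- co[, .(episode_id, person_id, index_date)]
  cond <- as.data.table(bundle$condition_occurrence)
  drug <- as.data.table(bundle$drug_exposure)
  visits <- as.data.table(bundle$visit_occurrence)

  events <- rbindlist(list(
    cond[, .(person_id, concept_code, date)],
    drug[, .(person_id, concept_code, date = start_date)],
    visits[, .(person_id,
               concept_code = paste0("SPEC-", provider_specialty),
               date = visit_date)]
  ))

  ev <- events[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
  ev[, lag_days := index_date - date]
  ev[, window := NA_character_]
  for (nm in names(windows)) {
    ev[lag_days >= windows[[nm]][1] & lag_days <= windows[[nm]][2],
       window := nm]
  }
  ev <- ev[!is.na(window)]
  out <- key[, .(episode_id)]
  if (nrow(ev)) {
    ev[, col_name := paste0("auto_", concept_code, "_", window)]
    wide <- dcast(ev, episode_id ~ col_name, fun.aggregate = length,
                  value.var = "window")
    cols <- setdiff(names(wide), "episode_id")
    for (cn in cols) set(wide, j = cn, value = as.numeric(wide[[cn]] > 0))
    out <- wide[out, on = "episode_id"]
    for (cn in cols) set(out, which(is.na(out[[cn]])), cn, 0)
    prev <- vapply(cols, function(cn) mean(out[[cn]]), 0)
    drop <- cols[prev < min_prevalence]
    if (length(drop)) out[, (drop) := NULL]
  }
  setcolorder(out, "episode_id")
  out <- out[co[, .(episode_id)], on = "episode_id"]
  cols <- setdiff(names(out), "episode_id")
  meta <- if (length(cols)) {
    data.table(
      column = cols, source = "auto",
      concept = sub("^auto_(.*)_([^_]+_[0-9]+m)$", "\\1", cols),
      window = sub("^auto_.*_((0_6|6_12|12_24)m)$", "\\1", cols)
    )
  } else {
    data.table(column = character(), source = character(),
               concept = character(), window = character())
  }
  new_feature_matrix(out, meta)
}

#' Summarize a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @return a data.table with one row per column: its prevalence (binary
#'   columns) or mean, window tag and source.
#' @export
feature_report <- function(fm) {
  meta <- fm_meta(fm)
  cols <- setdiff(names(fm), "episode_id")
  vals <- vapply(cols, function(cn) mean(as.data.frame(fm)[[cn]]), 0)
  rep_dt <- data.table(column = cols, prevalence_or_mean = unname(vals))
  if (!is.null(meta) && nrow(meta)) {
    rep_dt <- meta[rep_dt, on = "column"]
    setcolorder(rep_dt, c("column", "prevalence_or_mean", "window", "source"))
  }
  rep_dt
}
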