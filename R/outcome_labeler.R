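# Endpoint labeling: binary outcomes in fixed post-index windows with an
# observation indicator for right-censoring on plan exit.
#
# Y = 1 iff a qualifying diagnosis occurs strictly after the index day and
# no later than `window_days` after it (index-day events are contemporaneous
# with the treatment decision, not outcomes). D = 1 iff the person stays
# enrolled through the full window; when D = 0 the outcome is missing, and
# downstream estimation reweights the observed by 1/pi(X).

#' Define an endpoint
#'
#' @param name endpoint name.
#' @param event_codes diagnosis codes that count as the event.
#' @param window_days follow-up window length in days.
#' @param visit_scope `"any"`, `"inpatient_only"`, or `"outpatient_only"`:
#'   which visit context a qualifying diagnosis must carry.
#' @param family `"failure"`, `"adverse"`, or `"negative_control"`.
#' @return an object of class `endpoint_spec`.
#' @export
endpoint_spec <- function(name, event_codes, window_days,
                          visit_scope = c("any", "inpatient_only",
                                          "outpatient_only"),
                          family = c("failure", "adverse",
                                     "negative_control")) {
  visit_scope <- match.arg(visit_scope)
  family <- match.arg(family)
  stopifnot(window_days > 0, length(event_codes) >= 1)
  structure(
    list(name = name, event_codes = event_codes,
         window_days = as.integer(window_days),
         visit_scope = visit_scope, family = family),
    class = "endpoint_spec"
  )
}

#' The full default endpoint battery
#'
#' Composite treatment failure (UTI, pyelonephritis or sepsis revisit
#' within 30 days, any setting), its three subtype endpoints, an
#' inpatient-only composite, the adverse-event endpoints (diarrhea within
#' 15 days; acute kidney injury and dermatologic events within 30 days;
#' C. difficile within 90 days), and the three negative-control outcomes
#' (fibrocystic breast disease, hernia, fracture) each at 30 and 90 days
#' (1 and 3 months with the month = 30 days convention).
#'
#' @param codes a code-list config shaped like [default_codes()].
#' @return a named list of [endpoint_spec()] objects (15 in total).
#' @export
default_endpoints <- function(codes = default_codes()) {
  composite <- c(codes$uti, codes$pyelonephritis, codes$sepsis)
  specs <- list(
    endpoint_spec("composite_failure", composite, 30, "any", "failure"),
    endpoint_spec("failure_uti", codes$uti, 30, "any", "failure"),
    endpoint_spec("failure_pyelonephritis", codes$pyelonephritis, 30,
                  "any", "failure"),
    endpoint_spec("failure_sepsis", codes$sepsis, 30, "any", "failure"),
    endpoint_spec("failure_inpatient", composite, 30, "inpatient_only",
                  "failure"),
    endpoint_spec("diarrhea", codes$adverse_events$diarrhea, 15, "any",
                  "adverse"),
    endpoint_spec("acute_kidney_injury",
                  codes$adverse_events$acute_kidney_injury, 30, "any",
                  "adverse"),
    endpoint_spec("dermatologic", codes$adverse_events$dermatologic, 30,
                  "any", "adverse"),
    endpoint_spec("c_difficile", codes$adverse_events$c_difficile, 90,
                  "any", "adverse")
  )
  for (nc in names(codes$negative_controls)) {
    if (is.null(codes$negative_controls[[nc]])) {
      stop("missing code list for negative control '", nc, "'")
    }
    for (w in c(30L, 90L)) {
      specs[[length(specs) + 1L]] <- endpoint_spec(
        sprintf("nc_%s_%dd", nc, w), codes$negative_controls[[nc]], w,
        "any", "negative_control")
    }
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Label one endpoint for every episode
#'
#' @param cohort episode rows to label (typically eligible episodes).
#' @param bundle the claims bundle.
#' @param spec an [endpoint_spec()].
#' @return a data.table `(episode_id, D, Y)` where `D = 1` iff enrollment
#'   covers the full window (and the window fits inside the study period)
#'   and `Y` is the binary outcome, `NA` when `D = 0`.
#' @export
label_outcome <- function(cohort, bundle, spec) {
  stopifnot(inherits(spec, "endpoint_spec"))
  co <- as.data.table(cohort)
  key <- co[, .(episode_id, person_id, index_date)]
  obs <- as.data.table(bundle$observation_period)
  cond <- as.data.table(bundle$condition_occurrence)

  m <- obs[key, on = "person_id"]
  D <- as.integer(!is.na(m$enroll_end) &
                    m$enroll_end >= m$index_date + spec$window_days)
  # windows that run past the study period cannot be fully observed
  if (!is.null(bundle$meta$total_days)) {
    D[m$index_date + spec$window_days > bundle$meta$total_days] <- 0L
  }

  ev <- cond[concept_code %in% spec$event_codes]
  if (spec$visit_scope == "inpatient_only") {
    ev <- ev[visit_context == "inpatient"]
  } else if (spec$visit_scope == "outpatient_only") {
    ev <- ev[visit_context == "outpatient"]
  }
  me <- ev[key, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
  me[, lag_days := date - index_date]
  hit <- unique(me[lag_days >= 1L & lag_days <= spec$window_days, episode_id])

  Y <- as.integer(key$episode_id %in% hit)
  Y[D == 0L] <- NA_integer_
  data.table(episode_id = key$episode_id, D = D, Y = Y)
}

#' Label a battery of endpoints
#'
#' @inheritParams label_outcome
#' @param specs a list of [endpoint_spec()]s, e.g. [default_endpoints()].
#' @return a data.table with `episode_id` and, per endpoint `name`,
#'   columns `D_<name>` and `Y_<name>`.
#' @export
label_outcomes <- function(cohort, bundle, specs) {
  out <- data.table(episode_id = as.data.table(cohort)$episode_id)
  for (spec in specs) {
    lab <- label_outcome(cohort, bundle, spec)
    out[[paste0("D_", spec$name)]] <- lab$D
    out[[paste0("Y_", spec$name)]] <- lab$Y
  }
  out
}
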