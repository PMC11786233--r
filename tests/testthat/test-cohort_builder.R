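# Episode identification and the exclusion cascade, checked against
# hand-enumerated fixtures.


test_that("diagnoses within the gap collapse into one episode", {
  b <- make_bundle(
    person = fx_person(1L),
    condition = dtb(person_id = 1L, concept_code = "C-UTI",
                    date = c(800L, 803L, 810L), visit_context = "outpatient"))
  ep <- identify_episodes(b, cohort_config())
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$index_date, 800L)

  b2 <- make_bundle(
    person = fx_person(1L),
    condition = dtb(person_id = 1L, concept_code = "C-UTI",
                    date = c(800L, 860L), visit_context = "outpatient"))
  expect_equal(nrow(identify_episodes(b2, cohort_config())), 2L)
})

test_that("a five-person fixture yields the hand-counted episode list", {
  cond <- data.table::rbindlist(list(
    dtb(person_id = 1L, concept_code = "C-UTI",
        date = c(100L, 120L, 140L), visit_context = "outpatient"),
    dtb(person_id = 2L, concept_code = "C-UTI",
        date = c(100L, 200L), visit_context = "outpatient"),
    dtb(person_id = 3L, concept_code = "C-UTI",
        date = 150L, visit_context = "outpatient"),
    dtb(person_id = 4L, concept_code = "C-UTI",
        date = 100L, visit_context = "inpatient"),   # must not seed
    dtb(person_id = 5L, concept_code = "C-UTI",
        date = c(100L, 131L), visit_context = "outpatient")
  ))
  b <- make_bundle(person = data.table::rbindlist(lapply(1:5, fx_person)),
                   condition = cond)
  ep <- identify_episodes(b, cohort_config())
  got <- ep[, .(person_id, index_date)][order(person_id, index_date)]
  expect_equal(
    as.data.frame(got),
    data.frame(person_id = c(1L, 2L, 2L, 3L, 5L, 5L),
               index_date = c(100L, 100L, 200L, 150L, 100L, 131L)))
})

test_that("empty UTI code lists and empty condition tables are rejected", {
  b <- make_bundle(person = fx_person(1L))
  expect_error(identify_episodes(b, cohort_config()), "empty")
  cfg <- cohort_config()
  cfg$codes$uti <- character()
  b2 <- cascade_fixture()
  expect_error(identify_episodes(b2, cfg), "empty UTI code list")
})

test_that("treatment assignment follows the dispensing window and flags", {
  mk <- function(drug) make_bundle(
    person = fx_person(1L),
    condition = dtb(person_id = 1L, concept_code = "C-UTI", date = 800L,
                    visit_context = "outpatient"),
    drug = drug)
  cfg <- cohort_config()
  run <- function(b) assign_treatment(identify_episodes(b, cfg), b, cfg)

  # one first-line dispensing two days in: assigned, no flags
  co <- run(mk(dtb(person_id = 1L, concept_code = "D-NITRO",
                   drug_class = "first_line", start_date = 802L,
                   days_supply = 7L)))
  expect_equal(co$treatment_class, "first_line")
  expect_equal(co$T_ind, 1L)
  expect_false(co$excl_multi_drug | co$excl_washout | co$excl_no_treatment |
                 co$excl_off_list)

  # two covered classes inside the window: multi-antibiotic flag
  co <- run(mk(dtb(person_id = 1L,
                   concept_code = c("D-CIPRO", "D-CEFADROX"),
                   drug_class = c("fluoroquinolone", "beta_lactam"),
                   start_date = c(801L, 805L), days_supply = 7L)))
  expect_true(co$excl_multi_drug)
  expect_true(is.na(co$treatment_class))

  # antibiotic 3 days before the index: washout flag
  co <- run(mk(dtb(person_id = 1L,
                   concept_code = c("D-AMOXCLAV", "D-NITRO"),
                   drug_class = c("beta_lactam", "first_line"),
                   start_date = c(797L, 801L), days_supply = 7L)))
  expect_true(co$excl_washout)
  expect_equal(co$treatment_class, "first_line")

  # boundary days: index day and day +7 count, day +8 does not
  co <- run(mk(dtb(person_id = 1L, concept_code = "D-NITRO",
                   drug_class = "first_line", start_date = 800L,
                   days_supply = 7L)))
  expect_equal(co$treatment_class, "first_line")
  co <- run(mk(dtb(person_id = 1L, concept_code = "D-NITRO",
                   drug_class = "first_line", start_date = 807L,
                   days_supply = 7L)))
  expect_equal(co$treatment_class, "first_line")
  co <- run(mk(dtb(person_id = 1L, concept_code = "D-NITRO",
                   drug_class = "first_line", start_date = 808L,
                   days_supply = 7L)))
  expect_true(co$excl_no_treatment)

  # off-list antibiotic in the window
  co <- run(mk(dtb(person_id = 1L, concept_code = "D-FLUCON",
                   drug_class = "off_list", start_date = 801L,
                   days_supply = 7L)))
  expect_true(co$excl_off_list)
})

test_that("recurrence windows follow the configured and/or rule", {
  mk_cohort <- function(days, rule) {
    b <- make_bundle(
      person = fx_person(1L),
      condition = dtb(person_id = 1L, concept_code = "C-UTI", date = days,
                      visit_context = "outpatient"))
    cfg <- cohort_config(recurrent_rule = rule)
    suppressWarnings(flag_recurrent(identify_episodes(b, cfg), cfg))
  }
  # single episode: never recurrent
  expect_false(mk_cohort(800L, "and")$excl_recurrent)

  # 0/100/150: the day-150 episode has 3 in 180 days, satisfying both
  co <- mk_cohort(c(800L, 900L, 950L), "and")
  expect_equal(co[order(index_date)]$excl_recurrent, c(FALSE, FALSE, TRUE))

  # 0/90 only: conjunctive rule never fires, disjunctive flags day 90
  expect_false(any(mk_cohort(c(800L, 890L), "and")$excl_recurrent))
  co <- mk_cohort(c(800L, 890L), "or")
  expect_equal(co[order(index_date)]$excl_recurrent, c(FALSE, TRUE))
})

test_that("the conjunctive recurrent default is announced", {
  b <- make_bundle(
    person = fx_person(1L),
    condition = dtb(person_id = 1L, concept_code = "C-UTI", date = 800L,
                    visit_context = "outpatient"))
  cfg <- cohort_config()
  expect_warning(flag_recurrent(identify_episodes(b, cfg), cfg),
                 "recurrent")
})

test_that("complicated flags honor the two lookback regimes and sex", {
  mk <- function(extra_cond = NULL, sex = "F") {
    cond <- dtb(person_id = 1L, concept_code = "C-UTI", date = 900L,
                visit_context = "outpatient")
    if (!is.null(extra_cond)) cond <- rbind(cond, dtb(extra_cond))
    make_bundle(person = fx_person(1L, sex = sex), condition = cond)
  }
  cfg <- cohort_config()
  run <- function(b) flag_complicated(identify_episodes(b, cfg), b, cfg)

  # long-term comorbidity two years before the index still flags
  co <- run(mk(list(person_id = 1L, concept_code = "C-NEUROBLADDER",
                    date = 170L, visit_context = "outpatient")))
  expect_true(co$excl_complicated)

  # acute complicating code outside its 180-day lookback does not
  co <- run(mk(list(person_id = 1L, concept_code = "C-STONE",
                    date = 600L, visit_context = "outpatient")))
  expect_false(co$excl_complicated)
  co <- run(mk(list(person_id = 1L, concept_code = "C-STONE",
                    date = 800L, visit_context = "outpatient")))
  expect_true(co$excl_complicated)

  # male sex always flags; a clean history never does
  expect_true(run(mk(sex = "M"))$excl_complicated)
  expect_false(run(mk())$excl_complicated)

  # pregnancy code within 280 days
  co <- run(mk(list(person_id = 1L, concept_code = "C-PREGNANCY",
                    date = 700L, visit_context = "outpatient")))
  expect_true(co$excl_pregnancy)
})

test_that("the cascade fixture attributes exactly one removal per rule", {
  b <- cascade_fixture()
  co <- build_cohort(b)
  expect_equal(nrow(co), 25L)
  rep <- attrition_report(co)
  expect_equal(rep$episodes_remaining[1], 25L)
  removed <- setNames(rep$episodes_removed[-1], rep$rule[-1])
  expect_equal(removed[c("male", "underage", "washout", "recurrent",
                         "complicated", "multi_drug", "off_list")],
               c(male = 1L, underage = 1L, washout = 1L, recurrent = 1L,
                 complicated = 1L, multi_drug = 1L, off_list = 1L))
  expect_equal(removed[["no_treatment"]], 0L)
  expect_equal(removed[["pregnancy"]], 0L)
  # conservation: removals plus the final count give back the start
  expect_equal(sum(rep$episodes_removed) + rep$episodes_remaining[nrow(rep)],
               25L)
  expect_equal(sum(co$eligible), 18L)
})

test_that("eligibility does not depend on rule-evaluation order", {
  b <- cascade_fixture()
  co <- build_cohort(b)
  flags <- as.data.frame(co)[paste0("excl_", uticausal:::exclusion_rules())]
  eligible_ref <- co$eligible
  set.seed(1)
  for (k in 1:5) {
    perm <- sample(names(flags))
    keep <- rep(TRUE, nrow(co))
    for (f in perm) keep <- keep & !flags[[f]]
    expect_identical(keep & !is.na(co$treatment_class), eligible_ref)
  }
})

test_that("re-running the cascade on a finalized cohort changes nothing", {
  b <- cascade_fixture()
  cfg <- cohort_config()
  co1 <- build_cohort(b, cfg)
  co2 <- finalize_eligibility(
    flag_complicated(
      suppressWarnings(flag_recurrent(
        assign_treatment(co1, b, cfg), cfg)), b, cfg))
  expect_equal(as.data.frame(co2), as.data.frame(co1), ignore_attr = TRUE)
})

test_that("injected exclusion rates are recovered within binomial error", {
  rates <- c(washout = 0.06, complicated = 0.08, pregnancy = 0.03)
  b <- simulate_claims(quick_sim(n = 8000, seed = 17, prop_female = 1,
                                 prior_uti_rate = 0,
                                 exclusion_injection_rates = rates))
  co <- build_cohort(b)
  for (r in names(rates)) {
    got <- mean(co[[paste0("excl_", r)]])
    tol <- 3 * sqrt(rates[[r]] * (1 - rates[[r]]) / 8000)
    expect_lt(abs(got - rates[[r]]), tol + 0.002, label = r)
  }
})

test_that("contrast restriction errors on an absent arm", {
  b <- simulate_claims(quick_sim(n = 400, seed = 23))
  co <- build_cohort(b)
  expect_error(contrast_cohort(co, "beta_lactam"), "empty")
  cc <- contrast_cohort(co, "fluoroquinolone")
  expect_true(all(cc$T_ind %in% 0:1))
  expect_true(all(cc$eligible))
})
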