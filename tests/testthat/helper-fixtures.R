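# Shared fixtures: hand-built claims bundles small enough to enumerate by
# hand, and compact simulation configs for property tests.

# data.table constructor that also accepts a single plain list of columns
dtb <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !data.table::is.data.table(args[[1]])) {
    data.table::as.data.table(args[[1]])
  } else {
    data.table::data.table(...)
  }
}

# Assemble a claims_bundle from partial tables; anything omitted is empty.
# Dates are integer day offsets from 2012-01-01, as in simulated bundles.
make_bundle <- function(person = NULL, condition = NULL, drug = NULL,
                        visit = NULL, measurement = NULL, obs = NULL,
                        truth = NULL, total_days = 3652L) {
  dt <- dtb
  empty <- list(
    person = dt(person_id = integer(), sex = character(),
                birth_year = integer()),
    condition_occurrence = dt(person_id = integer(),
                              concept_code = character(), date = integer(),
                              visit_context = character()),
    drug_exposure = dt(person_id = integer(), concept_code = character(),
                       drug_class = character(), start_date = integer(),
                       days_supply = integer()),
    visit_occurrence = dt(person_id = integer(), visit_date = integer(),
                          visit_type = character(),
                          provider_specialty = character()),
    measurement = dt(person_id = integer(), measurement_type = character(),
                     date = integer()),
    observation_period = dt(person_id = integer(), enroll_start = integer(),
                            enroll_end = integer())
  )
  b <- empty
  if (!is.null(person)) b$person <- dt(person)
  if (!is.null(condition)) b$condition_occurrence <- dt(condition)
  if (!is.null(drug)) b$drug_exposure <- dt(drug)
  if (!is.null(visit)) b$visit_occurrence <- dt(visit)
  if (!is.null(measurement)) b$measurement <- dt(measurement)
  if (!is.null(obs)) {
    b$observation_period <- dt(obs)
  } else if (!is.null(person)) {
    b$observation_period <- dt(person_id = b$person$person_id,
                               enroll_start = 0L, enroll_end = total_days)
  }
  b$truth <- truth
  b$meta <- list(study_start = as.Date("2012-01-01"),
                 total_days = total_days, simulated = !is.null(truth))
  structure(b, class = "claims_bundle")
}

# A person row: adult woman born 1970 unless overridden.
fx_person <- function(id, sex = "F", birth_year = 1970L) {
  list(person_id = id, sex = sex, birth_year = birth_year)
}

# Outpatient UTI diagnosis + matching visit + first-line dispensing one day
# later: the minimal eligible episode.
fx_episode_rows <- function(id, index, drug_code = "D-NITRO",
                            drug_class = "first_line", drug_day = index + 1L,
                            specialty = "family_medicine") {
  list(
    condition = list(person_id = id, concept_code = "C-UTI",
                     date = index, visit_context = "outpatient"),
    visit = list(person_id = id, visit_date = index,
                 visit_type = "outpatient", provider_specialty = specialty),
    drug = list(person_id = id, concept_code = drug_code,
                drug_class = drug_class, start_date = drug_day,
                days_supply = 7L)
  )
}

# The 25-episode cascade fixture: 16 clean single-episode persons, one
# exemplar person per exclusion rule (male, under-age, washout,
# multi-antibiotic, complicated, off-list), and one recurrent person whose
# third episode in 180 days is the only recurrent-flagged one. Exactly one
# episode is removed per rule; 18 remain eligible.
cascade_fixture <- function() {
  rbl <- data.table::rbindlist
  persons <- list()
  conds <- list()
  visits <- list()
  drugs <- list()
  add_ep <- function(id, index, ...) {
    e <- fx_episode_rows(id, index, ...)
    conds[[length(conds) + 1L]] <<- e$condition
    visits[[length(visits) + 1L]] <<- e$visit
    drugs[[length(drugs) + 1L]] <<- e$drug
  }

  for (id in 1:16) {                     # clean eligible episodes
    persons[[id]] <- fx_person(id)
    add_ep(id, 800L + 40L * id)
  }
  persons[[17]] <- fx_person(17L, sex = "M")         # male
  add_ep(17L, 900L)
  persons[[18]] <- fx_person(18L, birth_year = 1998L)  # age 16 at index
  add_ep(18L, 900L)
  persons[[19]] <- fx_person(19L)                    # washout violation
  add_ep(19L, 900L)
  drugs[[length(drugs) + 1L]] <- list(
    person_id = 19L, concept_code = "D-CIPRO", drug_class = "fluoroquinolone",
    start_date = 897L, days_supply = 7L)
  persons[[20]] <- fx_person(20L)                    # multi-antibiotic
  add_ep(20L, 900L)
  drugs[[length(drugs) + 1L]] <- list(
    person_id = 20L, concept_code = "D-CEFPOD", drug_class = "beta_lactam",
    start_date = 904L, days_supply = 7L)
  persons[[21]] <- fx_person(21L)                    # complicated (long-term)
  add_ep(21L, 900L)
  conds[[length(conds) + 1L]] <- list(
    person_id = 21L, concept_code = "C-NEUROBLADDER", date = 150L,
    visit_context = "outpatient")
  persons[[22]] <- fx_person(22L)                    # off-list drug
  add_ep(22L, 900L, drug_code = "D-FLUCON", drug_class = "off_list")
  persons[[23]] <- fx_person(23L)                    # recurrent (3rd of 3)
  add_ep(23L, 800L)
  add_ep(23L, 870L)
  add_ep(23L, 940L)

  make_bundle(person = rbl(persons), condition = rbl(conds),
              visit = rbl(visits), drug = rbl(drugs))
}

# Small simulation config with every injection switched off.
quick_sim <- function(n = 2000L, seed = 1L, ...) {
  sim_config(n_persons = n, seed = seed, ...)
}
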