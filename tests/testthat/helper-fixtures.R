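# Hand-built micro-populations with known timelines, and random valid
# populations for property tests.

make_patients <- function(ids, birth = -20000L, death = NA_integer_,
                          gender = "FEMALE", race = "WHITE",
                          ethnicity = "NON_HISPANIC") {
  tibble::tibble(patient_id = ids, birth_date = birth, gender = gender,
                 race = race, ethnicity = ethnicity, death_date = death)
}

# events from a compact spec: encounter dates plus optional coded events
make_events <- function(patient_id, enc_dates = integer(),
                        enc_types = "OUTPATIENT",
                        codes = NULL) {
  enc <- if (length(enc_dates) > 0) {
    types <- rep_len(enc_types, length(enc_dates))
    tibble::tibble(patient_id = patient_id, date = as.integer(enc_dates),
                   category = "ENCOUNTER", code = types,
                   encounter_type = types)
  }
  coded <- if (!is.null(codes)) {
    tibble::tibble(patient_id = patient_id, date = as.integer(codes$date),
                   category = codes$category, code = codes$code,
                   encounter_type = NA_character_)
  }
  empty <- tibble::tibble(patient_id = character(), date = integer(),
                          category = character(), code = character(),
                          encounter_type = character())
  dplyr::bind_rows(empty, enc, coded)
}

# single-patient population: encounters at `enc_dates`, optional coded events
one_patient <- function(enc_dates, death = NA_integer_, codes = NULL,
                        enc_types = "OUTPATIENT", id = "pat1",
                        birth = -20000L, gender = "FEMALE") {
  ehr_population(
    make_patients(id, death = death, birth = birth, gender = gender),
    make_events(id, enc_dates, enc_types = enc_types, codes = codes)
  )
}

# a small deterministic multi-patient population exercising both cases
toy_population <- function() {
  p1 <- make_patients("alice", death = 900L)            # positive candidate
  p2 <- make_patients("bob")                            # negative candidate
  p3 <- make_patients("carol", death = 300L)            # infeasible positive
  ev <- dplyr::bind_rows(
    make_events("alice", c(0, 100, 450, 600, 700, 850)),
    make_events("bob", c(0, 200, 500, 600, 1100)),
    make_events("carol", c(0, 50, 150))
  )
  ehr_population(dplyr::bind_rows(p1, p2, p3), ev)
}

# cohort for a single hand-built instance: window events given as offsets
# back from the prediction date
instance_fixture <- function(pd = 2000L, offsets_codes = NULL,
                             enc_offsets = integer(), enc_types = "OUTPATIENT",
                             birth = -20000L, gender = "FEMALE",
                             id = "pat1") {
  codes <- if (!is.null(offsets_codes)) {
    tibble::tibble(date = pd - offsets_codes$offset,
                   category = offsets_codes$category,
                   code = offsets_codes$code)
  }
  first_enc <- max(pd - 400L, birth)  # history start, never before birth
  pop <- ehr_population(
    make_patients(id, birth = birth, gender = gender),
    make_events(id, c(first_enc, pd - enc_offsets),
                enc_types = c("OUTPATIENT", rep_len(enc_types, length(enc_offsets))),
                codes = codes)
  )
  structure(list(
    instances = tibble::tibble(patient_id = id, prediction_date = pd,
                               label = 0L, admitted = FALSE,
                               censor_length = NA_integer_),
    events = pop$events,
    patients = pop$patients,
    exclusions = tibble::tibble(patient_id = character(), reason = character())
  ), class = "mortality_cohort")
}

# random valid population, small and fast, for round-trip/property tests
random_population <- function(seed, n = 30) {
  generate_population(sim_config(
    n_patients = n, seed = seed, calendar_span_days = 1500L,
    encounter_rate_per_year = 6, p_inpatient = 0.05,
    vocab_sizes = c(ICD9 = 20L, CPT = 10L, RXCUI = 10L),
    baseline_annual_death_hazard = 0.1
  ))
}

# a hand-assembled logistic model over an explicit vocabulary, for
# closed-form checks
manual_logistic_model <- function(vocabulary, weights, bias = 0) {
  w <- rep(0, nrow(vocabulary))
  w[match(names(weights), vocabulary$feature)] <- unlist(weights)
  palliascreen:::new_mortality_model(
    weights = list(W = list(matrix(w, ncol = 1)), b = list(bias)),
    config = model_config(input_dim = nrow(vocabulary), hidden_layers = 0,
                          hidden_width = 1, max_iterations = 1),
    feature_names = vocabulary$feature
  )
}

# vocabulary straight from a feature table, no pruning
vocab_of <- function(cohort) build_vocabulary(cohort, min_patient_support = 0L)
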