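#' Configure the synthetic-EHR generator
#'
#' Describes a synthetic population of longitudinal coded EHRs with a known,
#' planted mortality mechanism. Patients accrue encounters as a homogeneous
#' Poisson process over a fixed calendar span; each encounter emits an
#' ENCOUNTER event (one per day across an inpatient admission span) plus a
#' Poisson number of background ICD9/CPT/RXCUI codes. A designated set of
#' "risk codes" is carried by a random subset of patients; carriers emit their
#' risk codes at encounters and die under a proportional-hazards model whose
#' annual hazard is `baseline_annual_death_hazard * exp(r)` with
#' `r = sum(log_hazard_effect)` over carried codes. Deaths are recorded only
#' when they fall inside the calendar span; later deaths are unobserved, so
#' the population is right-censored at the end of the span exactly as a
#' warehouse snapshot would be.
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: a ten-year snapshot, about eight encounters per patient-year,
#' rare inpatient admissions, a low baseline annual death hazard, and five
#' planted ICD9 risk codes with log-hazard effects between 1.5 and 3, strong
#' enough that the count of planted codes in an observation window alone
#' ranks one-year deaths above survivors (univariate AUROC near 0.79). The
#' resulting cohorts have roughly 10-12% positive prevalence and 15-25%
#' admitted instances.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param calendar_span_days Length of the observed calendar, in days.
#' @param encounter_rate_per_year Poisson rate of encounters per patient-year.
#' @param p_inpatient Probability an encounter is an inpatient admission.
#' @param admission_length_mean_extra_days Mean number of admitted days beyond
#'   the first; admission length is `1 + Poisson(mean)` days.
#' @param vocab_sizes Named integer vector: background vocabulary sizes for
#'   `ICD9`, `CPT`, `RXCUI`.
#' @param risk_codes Data frame with columns `code`, `category`,
#'   `log_hazard_effect`: the planted mortality signal. May have zero rows.
#' @param risk_carrier_prob Per-code probability that a patient carries a
#'   risk code (independent across codes and patients).
#' @param risk_emit_prob Probability a carrier emits each carried risk code at
#'   any given encounter.
#' @param baseline_annual_death_hazard Annual death hazard for a patient
#'   carrying no risk codes, in (0, 1).
#' @param codes_per_encounter_mean Mean background codes emitted per encounter.
#'
#' @return A `sim_config` list, validated.
#' @seealso [generate_population()], [planted_truth()]
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       calendar_span_days = 3650L,
                       encounter_rate_per_year = 8,
                       p_inpatient = 0.003,
                       admission_length_mean_extra_days = 3,
                       vocab_sizes = c(ICD9 = 150L, CPT = 100L, RXCUI = 100L),
                       risk_codes = default_risk_codes(),
                       risk_carrier_prob = 0.03,
                       risk_emit_prob = 0.5,
                       baseline_annual_death_hazard = 0.002,
                       codes_per_encounter_mean = 4) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    calendar_span_days = as.integer(calendar_span_days),
    encounter_rate_per_year = encounter_rate_per_year,
    p_inpatient = p_inpatient,
    admission_length_mean_extra_days = admission_length_mean_extra_days,
    vocab_sizes = vocab_sizes,
    risk_codes = tibble::as_tibble(risk_codes),
    risk_carrier_prob = risk_carrier_prob,
    risk_emit_prob = risk_emit_prob,
    baseline_annual_death_hazard = baseline_annual_death_hazard,
    codes_per_encounter_mean = codes_per_encounter_mean
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted risk codes
#'
#' Five ICD9 risk codes with log-hazard effects spanning 1 to 3, i.e. hazard
#' ratios from about 2.7 to 20 over baseline — the range of a serious chronic
#' diagnosis up to a terminal one.
#'
#' @return Tibble with columns `code`, `category`, `log_hazard_effect`.
#' @export
default_risk_codes <- function() {
  tibble::tibble(
    code = sprintf("ICD9_R%02d", 1:5),
    category = "ICD9",
    log_hazard_effect = c(3.0, 3.5, 4.0, 4.5, 5.0)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) {
    if (!isTRUE(ok)) stop("invalid sim_config: ", msg, call. = FALSE)
  }
  stopifnot_cfg(length(cfg$n_patients) == 1 && !is.na(cfg$n_patients) && cfg$n_patients >= 0,
                "n_patients must be a non-negative integer")
  stopifnot_cfg(cfg$calendar_span_days > 0, "calendar_span_days must be positive")
  stopifnot_cfg(cfg$encounter_rate_per_year > 0, "encounter_rate_per_year must be positive")
  stopifnot_cfg(cfg$p_inpatient >= 0 && cfg$p_inpatient <= 1, "p_inpatient must be in [0,1]")
  stopifnot_cfg(cfg$admission_length_mean_extra_days >= 0,
                "admission_length_mean_extra_days must be non-negative")
  stopifnot_cfg(all(c("ICD9", "CPT", "RXCUI") %in% names(cfg$vocab_sizes)) &&
                  all(cfg$vocab_sizes[c("ICD9", "CPT", "RXCUI")] >= 1),
                "vocab_sizes must name positive ICD9/CPT/RXCUI sizes")
  stopifnot_cfg(cfg$risk_carrier_prob >= 0 && cfg$risk_carrier_prob <= 1,
                "risk_carrier_prob must be in [0,1]")
  stopifnot_cfg(cfg$risk_emit_prob >= 0 && cfg$risk_emit_prob <= 1,
                "risk_emit_prob must be in [0,1]")
  stopifnot_cfg(cfg$baseline_annual_death_hazard > 0 && cfg$baseline_annual_death_hazard < 1,
                "baseline_annual_death_hazard must be in (0,1)")
  stopifnot_cfg(cfg$codes_per_encounter_mean >= 0,
                "codes_per_encounter_mean must be non-negative")
  rc <- cfg$risk_codes
  stopifnot_cfg(all(c("code", "category", "log_hazard_effect") %in% names(rc)),
                "risk_codes needs code/category/log_hazard_effect columns")
  stopifnot_cfg(all(rc$category %in% c("ICD9", "CPT", "RXCUI")),
                "risk_codes categories must be coded categories")
  stopifnot_cfg(!anyDuplicated(paste(rc$category, rc$code)), "duplicate risk codes")
  invisible(cfg)
}

#' The planted mortality signal of a simulation
#'
#' Returns the map from risk code to its log hazard effect, exactly as
#' configured. Downstream tests compare recovered signal (model coefficients,
#' explanation rankings) against this ground truth.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `code`, `category`, `log_hazard_effect`.
#' @export
planted_truth <- function(config) {
  validate_sim_config(config)
  tibble::as_tibble(config$risk_codes)
}

#' Generate a synthetic EHR population
#'
#' Samples a population under the mechanism described in [sim_config()].
#' Deterministic given `config$seed`; the ambient RNG state is left untouched.
#' The output always satisfies [validate_population()]: events stop at death,
#' birth precedes all events, and inpatient admissions appear as one
#' `ENCOUNTER`/`INPATIENT` event per admitted day (so the number of admitted
#' days in a window is directly countable).
#'
#' @param config A [sim_config()].
#' @return An [ehr_population()].
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  with_preserved_seed({
    set.seed(config$seed)
    generate_population_impl(config)
  })
}

generate_population_impl <- function(cfg) {
  n <- cfg$n_patients
  empty <- function() {
    ehr_population(
      tibble::tibble(patient_id = character(), birth_date = integer(),
                     gender = character(), race = character(),
                     ethnicity = character(), death_date = integer()),
      tibble::tibble(patient_id = character(), date = integer(),
                     category = character(), code = character(),
                     encounter_type = character()),
      validate = FALSE
    )
  }
  if (n == 0) return(empty())

  span <- cfg$calendar_span_days
  ids <- sprintf("P%06d", seq_len(n))

  # demographics: adults aged 30-90 at the start of the calendar
  age0 <- runif(n, 30, 90)
  patients <- tibble::tibble(
    patient_id = ids,
    birth_date = as.integer(-round(age0 * 365.25)),
    gender = sample(GENDERS, n, replace = TRUE, prob = c(0.48, 0.48, 0.04)),
    race = sample(c("WHITE", "BLACK", "ASIAN", "OTHER"), n, replace = TRUE,
                  prob = c(0.55, 0.15, 0.2, 0.1)),
    ethnicity = sample(c("HISPANIC", "NON_HISPANIC"), n, replace = TRUE,
                       prob = c(0.2, 0.8))
  )

  # planted risk: carrier indicators, latent log-hazard r, exponential death time
  rc <- cfg$risk_codes
  k <- nrow(rc)
  carrier <- matrix(0L, n, max(k, 1L))
  if (k > 0) {
    carrier <- matrix(rbinom(n * k, 1L, cfg$risk_carrier_prob), n, k)
  }
  r <- if (k > 0) drop(carrier %*% rc$log_hazard_effect) else rep(0, n)
  hazard <- cfg$baseline_annual_death_hazard * exp(r)
  t_years <- rexp(n, rate = hazard)
  death_day <- as.integer(ceiling(t_years * 365))
  died <- death_day <= span
  patients$death_date <- ifelse(died, death_day, NA_integer_)

  # encounters: homogeneous Poisson process up to death (or span end)
  horizon <- pmin(span, ifelse(died, death_day, span))
  n_enc <- rpois(n, cfg$encounter_rate_per_year * horizon / 365)
  pat_of_enc <- rep.int(seq_len(n), n_enc)
  m <- length(pat_of_enc)
  if (m == 0) {
    pop <- ehr_population(patients,
                          tibble::tibble(patient_id = character(), date = integer(),
                                         category = character(), code = character(),
                                         encounter_type = character()),
                          validate = FALSE)
    return(pop)
  }
  enc_date <- as.integer(floor(runif(m) * (horizon[pat_of_enc] + 1L)))
  enc_date <- pmin(enc_date, horizon[pat_of_enc])

  inpat <- runif(m) < cfg$p_inpatient
  out_type <- sample(c("OUTPATIENT", "ER", "SCAN"), m, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15))

  # inpatient spans: one INPATIENT encounter-day event per admitted day,
  # truncated at the patient's horizon; de-duplicated per patient-day below
  adm_len <- 1L + rpois(sum(inpat), cfg$admission_length_mean_extra_days)
  adm_pat <- pat_of_enc[inpat]
  adm_start <- enc_date[inpat]
  adm_day_pat <- rep.int(adm_pat, adm_len)
  adm_day <- sequence(adm_len, from = adm_start, by = 1L)
  keep <- adm_day <= horizon[adm_day_pat]
  inpat_events <- tibble::tibble(
    patient_id = ids[adm_day_pat[keep]],
    date = as.integer(adm_day[keep]),
    category = "ENCOUNTER",
    code = "INPATIENT",
    encounter_type = "INPATIENT"
  )
  inpat_events <- dplyr::distinct(inpat_events, .data$patient_id, .data$date,
                                  .keep_all = TRUE)

  out_events <- tibble::tibble(
    patient_id = ids[pat_of_enc[!inpat]],
    date = enc_date[!inpat],
    category = "ENCOUNTER",
    code = out_type[!inpat],
    encounter_type = out_type[!inpat]
  )

  # background coded events: Poisson number per encounter, categories mixed,
  # codes uniform within category
  n_codes <- rpois(m, cfg$codes_per_encounter_mean)
  code_pat <- rep.int(pat_of_enc, n_codes)
  code_date <- rep.int(enc_date, n_codes)
  mc <- length(code_pat)
  bg_cat <- sample(c("ICD9", "CPT", "RXCUI"), mc, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
  bg_idx <- as.integer(ceiling(runif(mc) * cfg$vocab_sizes[bg_cat]))
  code_events <- tibble::tibble(
    patient_id = ids[code_pat],
    date = code_date,
    category = bg_cat,
    code = sprintf("%s_%04d", bg_cat, bg_idx),
    encounter_type = NA_character_
  )

  # risk-code emissions: at each encounter a carrier emits each carried code
  # independently with risk_emit_prob
  risk_events <- NULL
  if (k > 0 && any(carrier > 0)) {
    per_code <- lapply(seq_len(k), function(j) {
      at <- which(carrier[pat_of_enc, j] == 1L)
      if (length(at) == 0) return(NULL)
      emit <- at[runif(length(at)) < cfg$risk_emit_prob]
      if (length(emit) == 0) return(NULL)
      tibble::tibble(
        patient_id = ids[pat_of_enc[emit]],
        date = enc_date[emit],
        category = rc$category[j],
        code = rc$code[j],
        encounter_type = NA_character_
      )
    })
    risk_events <- dplyr::bind_rows(per_code)
  }

  events <- dplyr::bind_rows(inpat_events, out_events, code_events, risk_events)
  ehr_population(patients, events, validate = FALSE)
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
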