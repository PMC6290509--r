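# Temporal cohort construction.
#
# Each patient contributes at most one labeled instance. The prediction date
# (PD) splits the record into an observation window (features) and a virtual
# future (label = death within 365 days of PD). Candidate PDs are encounter
# dates under interval constraints that guarantee a well-defined label and a
# full year of history; inpatient candidates are preferred; for deceased
# patients the earliest candidate is taken, for survivors the latest. A PD
# that falls inside an inpatient admission is moved to the admission's second
# day. Month arithmetic is fixed at 3 months = 90 days, 12 months = 365 days,
# with inclusive bounds.

DAYS_3M <- 90L
DAYS_12M <- 365L

# Per-patient temporal summaries used by the candidate rules.
patient_timelines <- function(population) {
  ev <- population$events
  if (nrow(ev) == 0) {
    return(dplyr::mutate(population$patients,
                         first_encounter = NA_integer_,
                         last_event = NA_integer_))
  }
  enc <- dplyr::filter(ev, .data$category == "ENCOUNTER")
  enc_rng <- if (nrow(enc) > 0) {
    dplyr::summarise(dplyr::group_by(enc, .data$patient_id),
                     first_encounter = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), first_encounter = integer())
  }
  any_rng <- dplyr::summarise(dplyr::group_by(ev, .data$patient_id),
                              last_event = max(.data$date), .groups = "drop")
  dplyr::left_join(
    dplyr::left_join(population$patients, enc_rng, by = "patient_id"),
    any_rng, by = "patient_id"
  )
}

candidate_table <- function(population) {
  tl <- patient_timelines(population)
  enc <- dplyr::filter(population$events, .data$category == "ENCOUNTER")
  enc <- dplyr::distinct(enc, .data$patient_id, .data$date)
  cand <- dplyr::inner_join(enc, tl, by = "patient_id")
  cand <- dplyr::filter(cand, !is.na(.data$first_encounter))
  pos <- dplyr::filter(
    cand, !is.na(.data$death_date),
    .data$date >= .data$death_date - DAYS_12M,
    .data$date <= .data$death_date - DAYS_3M,
    .data$date >= .data$first_encounter + DAYS_12M
  )
  neg <- dplyr::filter(
    cand, is.na(.data$death_date),
    .data$date >= .data$first_encounter + DAYS_12M,
    .data$date <= .data$last_event - DAYS_12M
  )
  dplyr::bind_rows(
    dplyr::mutate(pos, case = "positive"),
    dplyr::mutate(neg, case = "negative")
  )
}

one_patient_pop <- function(patient) {
  if (inherits(patient, "ehr_population")) {
    stopifnot(nrow(patient$patients) == 1)
    return(patient)
  }
  stop("`patient` must be a single-patient ehr_population", call. = FALSE)
}

#' Candidate prediction dates for a deceased patient
#'
#' Encounter dates at least 90 days and at most 365 days before death, and at
#' least 365 days after the patient's first encounter (all bounds inclusive).
#' An instance anchored at such a date is a positive example: death occurs
#' 3-12 months into the virtual future.
#'
#' @param patient A single-patient [ehr_population()] whose patient has a
#'   recorded `death_date`.
#' @return Integer vector of candidate day indices, ascending.
#' @export
candidate_dates_positive <- function(patient) {
  pop <- one_patient_pop(patient)
  if (is.na(pop$patients$death_date)) {
    stop("candidate_dates_positive requires a patient with a death_date", call. = FALSE)
  }
  ct <- candidate_table(pop)
  sort(ct$date[ct$case == "positive"])
}

#' Candidate prediction dates for a surviving patient
#'
#' Encounter dates at least 365 days after the first encounter and at least
#' 365 days before the last recorded event (bounds inclusive), so at least a
#' year of label-validating follow-up exists after the prediction date.
#'
#' @param patient A single-patient [ehr_population()] without a `death_date`.
#' @return Integer vector of candidate day indices, ascending.
#' @export
candidate_dates_negative <- function(patient) {
  pop <- one_patient_pop(patient)
  if (!is.na(pop$patients$death_date)) {
    stop("candidate_dates_negative requires a patient without a death_date", call. = FALSE)
  }
  ct <- candidate_table(pop)
  sort(ct$date[ct$case == "negative"])
}

# Inpatient admission spans: runs of consecutive INPATIENT encounter days.
inpatient_spans <- function(population) {
  days <- dplyr::filter(population$events, .data$category == "ENCOUNTER",
                        .data$encounter_type == "INPATIENT")
  days <- dplyr::distinct(days, .data$patient_id, .data$date)
  if (nrow(days) == 0) {
    return(tibble::tibble(patient_id = character(), date = integer(),
                          span_start = integer()))
  }
  days <- dplyr::arrange(days, .data$patient_id, .data$date)
  days <- dplyr::group_by(days, .data$patient_id)
  days <- dplyr::mutate(days, run = .data$date - dplyr::row_number())
  days <- dplyr::group_by(days, .data$patient_id, .data$run)
  days <- dplyr::mutate(days, span_start = min(.data$date))
  days <- dplyr::ungroup(days)
  dplyr::select(days, "patient_id", "date", "span_start")
}

select_prediction_table <- function(population) {
  cand <- candidate_table(population)
  if (nrow(cand) == 0) {
    return(tibble::tibble(patient_id = character(), prediction_date = integer(),
                          admitted = logical(), case = character()))
  }
  spans <- inpatient_spans(population)
  cand <- dplyr::left_join(cand, spans, by = c("patient_id", "date"))
  cand <- dplyr::mutate(cand, inpat = !is.na(.data$span_start))

  # inpatient candidates are lexicographically preferred; then earliest for
  # positives, latest for negatives
  cand <- dplyr::group_by(cand, .data$patient_id)
  cand <- dplyr::filter(cand, if (any(.data$inpat)) .data$inpat else TRUE)
  picked <- dplyr::slice(
    dplyr::arrange(cand, .data$date, .by_group = TRUE),
    ifelse(dplyr::first(.data$case) == "positive", 1L, dplyr::n())
  )
  picked <- dplyr::ungroup(picked)

  # second-day adjustment for picks inside an admission, re-verified against
  # the case's interval constraints; on violation keep the original date
  adj <- picked$date
  adm <- picked$inpat
  second <- picked$span_start + 1L
  ok <- ifelse(
    picked$case == "positive",
    second >= picked$death_date - DAYS_12M &
      second <= picked$death_date - DAYS_3M &
      second >= picked$first_encounter + DAYS_12M,
    second >= picked$first_encounter + DAYS_12M &
      second <= picked$last_event - DAYS_12M
  )
  adj[adm & ok] <- second[adm & ok]
  tibble::tibble(patient_id = picked$patient_id,
                 prediction_date = as.integer(adj),
                 admitted = adm, case = picked$case)
}

#' Select the prediction date for one patient
#'
#' Applies the full selection rule: case-appropriate candidates
#' ([candidate_dates_positive()] / [candidate_dates_negative()]), restriction
#' to inpatient candidates when any exist, earliest (deceased) or latest
#' (surviving) pick, and the second-day-of-admission adjustment with
#' re-verification of the interval constraints (reverting to the picked date,
#' still flagged admitted, if the adjustment violates them).
#'
#' @param patient A single-patient [ehr_population()].
#' @return `NULL` when the patient has no feasible date; otherwise a list with
#'   `prediction_date` (integer day) and `admitted` (logical).
#' @export
select_prediction_date <- function(patient) {
  pop <- one_patient_pop(patient)
  res <- select_prediction_table(pop)
  if (nrow(res) == 0) return(NULL)
  list(prediction_date = res$prediction_date[[1]], admitted = res$admitted[[1]])
}

#' Build a labeled mortality cohort
#'
#' Selects one prediction date per eligible patient, censors each record at
#' its prediction date (events strictly after it are removed), and labels the
#' instance 1 when death occurs within 365 days of the prediction date.
#' Patients with no feasible date are excluded, not errors, and are accounted
#' for in the exclusion table. A censor-length column records follow-up past
#' the prediction date: time to death for positives, time to the last
#' recorded event for negatives.
#'
#' @param population An [ehr_population()].
#' @return A `mortality_cohort`: list with
#'   * `instances` — tibble `patient_id`, `prediction_date`, `label`,
#'     `admitted`, `censor_length` (and `split` after [split_cohort()]);
#'   * `events` — censored events of included patients;
#'   * `patients` — demographics of included patients;
#'   * `exclusions` — tibble `patient_id`, `reason`.
#' @export
build_cohort <- function(population) {
  sel <- select_prediction_table(population)
  pat <- population$patients
  tl <- patient_timelines(population)
  inst <- dplyr::inner_join(sel, tl, by = "patient_id")
  inst <- dplyr::mutate(
    inst,
    label = as.integer(!is.na(.data$death_date) &
                         .data$death_date - .data$prediction_date <= DAYS_12M),
    censor_length = as.integer(ifelse(
      !is.na(.data$death_date),
      .data$death_date - .data$prediction_date,
      .data$last_event - .data$prediction_date
    ))
  )
  inst <- dplyr::select(inst, "patient_id", "prediction_date", "label",
                        "admitted", "censor_length")
  inst <- dplyr::arrange(inst, .data$patient_id)

  excluded <- setdiff(pat$patient_id, inst$patient_id)
  exclusions <- tibble::tibble(
    patient_id = sort(excluded),
    reason = "no feasible prediction date"
  )

  ev <- dplyr::inner_join(population$events,
                          dplyr::select(inst, "patient_id", "prediction_date"),
                          by = "patient_id")
  ev <- dplyr::filter(ev, .data$date <= .data$prediction_date)
  ev <- dplyr::select(ev, -"prediction_date")

  structure(
    list(instances = inst,
         events = ev,
         patients = dplyr::semi_join(pat, inst, by = "patient_id"),
         exclusions = exclusions),
    class = "mortality_cohort"
  )
}

#' @export
print.mortality_cohort <- function(x, ...) {
  cat("<mortality_cohort> ", nrow(x$instances), " instances (",
      sum(x$instances$label), " positive, ",
      sum(x$instances$admitted), " admitted), ",
      nrow(x$exclusions), " patients excluded\n", sep = "")
  if ("split" %in% names(x$instances)) {
    print(table(x$instances$split))
  }
  invisible(x)
}

#' Split a cohort into train / validation / test
#'
#' Patient-level multinomial assignment with probabilities proportional to
#' `ratios` (default 8:1:1), deterministic given `seed`. The split is stored
#' as a `split` column on the instance table; the three groups are disjoint
#' by patient and cover the cohort.
#'
#' @param cohort A `mortality_cohort`.
#' @param ratios Positive length-3 numeric, train/validation/test weights.
#' @param seed Integer seed.
#' @return The cohort with `instances$split` set to
#'   `"train"`, `"validation"` or `"test"`.
#' @export
split_cohort <- function(cohort, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  n <- nrow(cohort$instances)
  splits <- with_preserved_seed({
    set.seed(as.integer(seed))
    sample(c("train", "validation", "test"), n, replace = TRUE,
           prob = ratios / sum(ratios))
  })
  cohort$instances$split <- splits
  cohort
}

#' Restrict a cohort to a split or to given patients
#'
#' @param cohort A `mortality_cohort`.
#' @param split Optional split name(s) to keep (requires [split_cohort()]).
#' @param patient_ids Optional patient ids to keep.
#' @return A `mortality_cohort` restricted accordingly.
#' @export
cohort_subset <- function(cohort, split = NULL, patient_ids = NULL) {
  inst <- cohort$instances
  if (!is.null(split)) {
    stopifnot("split" %in% names(inst))
    inst <- dplyr::filter(inst, .data$split %in% !!split)
  }
  if (!is.null(patient_ids)) {
    inst <- dplyr::filter(inst, .data$patient_id %in% !!patient_ids)
  }
  cohort$instances <- inst
  cohort$events <- dplyr::semi_join(cohort$events, inst, by = "patient_id")
  cohort$patients <- dplyr::semi_join(cohort$patients, inst, by = "patient_id")
  cohort
}

#' Empirical survival curve of censor lengths
#'
#' For each label, the fraction of instances whose censor length exceeds `t`,
#' evaluated at every observed censor length (and at 0). Positives drop to 0
#' by construction at t = 365: every positive dies within a year of its
#' prediction date. Negatives stay at 1 up to t = 365: each has at least a
#' year of recorded follow-up.
#'
#' @param cohort A `mortality_cohort` (or its instance tibble).
#' @return Tibble with columns `label`, `t`, `fraction_exceeding`.
#' @export
censor_length_curve <- function(cohort) {
  inst <- if (inherits(cohort, "mortality_cohort")) cohort$instances else tibble::as_tibble(cohort)
  out <- dplyr::group_by(inst, .data$label)
  out <- dplyr::reframe(out, {
    len <- .data$censor_length
    ts <- sort(unique(c(0L, len)))
    tibble::tibble(t = ts,
                   fraction_exceeding = vapply(ts, function(tt) mean(len > tt), 0))
  })
  dplyr::ungroup(out)
}

#' Plot censor-length survival curves
#'
#' @param cohort A `mortality_cohort`.
#' @return A ggplot object.
#' @export
plot_censor_lengths <- function(cohort) {
  curve <- censor_length_curve(cohort)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$fraction_exceeding,
                                      colour = factor(.data$label))) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 365, linetype = "dashed") +
    ggplot2::labs(x = "days past prediction date", y = "fraction exceeding",
                  colour = "label",
                  title = "Right-censor lengths by class") +
    ggplot2::theme_minimal()
}
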