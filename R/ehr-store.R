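#' @importFrom rlang .data
#' @importFrom stats rbinom rexp rpois runif setNames var
#' @importFrom utils head
NULL

# Closed code-category enumeration. ENCOUNTER events additionally carry an
# encounter type (INPATIENT / OUTPATIENT / ER / SCAN ...).
CODE_CATEGORIES <- c("ICD9", "CPT", "RXCUI", "ENCOUNTER")
GENDERS <- c("MALE", "FEMALE", "OTHER")

#' Code categories recognised by the event log
#'
#' The event log is restricted to a closed set of code categories: `ICD9`
#' diagnostic/billing codes, `CPT` procedure codes, `RXCUI` medication codes
#' and `ENCOUNTER` visit records. Codes themselves are opaque tokens.
#'
#' @return Character vector of category names.
#' @export
code_categories <- function() CODE_CATEGORIES

#' Construct an EHR population
#'
#' Bundles the two tables that make up a longitudinal coded EHR extract:
#' one row per patient (demographics plus an optional death date) and one row
#' per coded event. All dates are integer day indices on a common, arbitrary
#' epoch; `birth_date` may be negative (born before the epoch).
#'
#' @param patients Data frame with columns `patient_id`, `birth_date`,
#'   `gender` (`MALE`/`FEMALE`/`OTHER`), `race`, `ethnicity`, `death_date`
#'   (integer or `NA`).
#' @param events Data frame with columns `patient_id`, `date` (integer day,
#'   >= 0), `category` (one of [code_categories()]), `code`, and
#'   `encounter_type` (non-`NA` exactly when `category == "ENCOUNTER"`).
#' @param validate Check invariants with [validate_population()] and stop on
#'   the first violation. Default `TRUE`.
#'
#' @return An object of class `ehr_population`: a list with tibbles
#'   `$patients` (ordered by `patient_id`) and `$events` (ordered by
#'   `patient_id`, then `date`).
#' @seealso [read_event_log()], [write_event_log()], [generate_population()]
#' @export
ehr_population <- function(patients, events, validate = TRUE) {
  patients <- tibble::as_tibble(patients)
  events <- tibble::as_tibble(events)
  if (!"death_date" %in% names(patients)) patients$death_date <- NA_integer_
  if (!"encounter_type" %in% names(events)) events$encounter_type <- NA_character_
  patients <- dplyr::mutate(
    patients,
    patient_id = as.character(.data$patient_id),
    birth_date = as.integer(.data$birth_date),
    death_date = as.integer(.data$death_date)
  )
  events <- dplyr::mutate(
    events,
    patient_id = as.character(.data$patient_id),
    date = as.integer(.data$date),
    code = as.character(.data$code)
  )
  patients <- dplyr::arrange(patients, .data$patient_id)
  events <- dplyr::arrange(events, .data$patient_id, .data$date, .data$category, .data$code)
  pop <- structure(list(patients = patients, events = events),
                   class = "ehr_population")
  if (validate) {
    v <- validate_population(pop)
    if (nrow(v) > 0) {
      stop("invalid population: ", v$patient_id[1], ": ", v$rule[1],
           if (nrow(v) > 1) paste0(" (and ", nrow(v) - 1, " more violations)"),
           call. = FALSE)
    }
  }
  pop
}

#' @export
print.ehr_population <- function(x, ...) {
  cat("<ehr_population> ", nrow(x$patients), " patients, ",
      nrow(x$events), " events, ",
      sum(!is.na(x$patients$death_date)), " deceased\n", sep = "")
  invisible(x)
}

#' Validate an EHR population
#'
#' Checks every structural invariant of the event log: known categories,
#' non-empty codes, non-negative dates, encounter types present exactly on
#' ENCOUNTER events, events not after the patient's death date, and birth
#' dates no later than any event. Violations are returned, not raised.
#'
#' @param population An [ehr_population()].
#' @return Tibble with columns `patient_id` and `rule`; zero rows when the
#'   population is valid.
#' @export
validate_population <- function(population) {
  ev <- population$events
  pat <- population$patients
  bad <- list()
  viol <- function(ids, rule) tibble::tibble(patient_id = unique(ids), rule = rule)

  if (nrow(ev) > 0) {
    i <- !ev$category %in% CODE_CATEGORIES
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "unknown code category")))
    i <- is.na(ev$code) | ev$code == ""
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "empty code")))
    i <- is.na(ev$date) | ev$date < 0L
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "negative or missing event date")))
    enc <- ev$category == "ENCOUNTER"
    i <- enc & (is.na(ev$encounter_type) | ev$encounter_type == "")
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "ENCOUNTER event without encounter_type")))
    i <- !enc & !is.na(ev$encounter_type)
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "encounter_type on non-ENCOUNTER event")))
    i <- !ev$patient_id %in% pat$patient_id
    if (any(i)) bad <- c(bad, list(viol(ev$patient_id[i], "event for unknown patient")))
  }
  i <- !pat$gender %in% GENDERS
  if (any(i)) bad <- c(bad, list(viol(pat$patient_id[i], "unknown gender")))
  if (anyDuplicated(pat$patient_id)) {
    bad <- c(bad, list(viol(pat$patient_id[duplicated(pat$patient_id)],
                            "duplicate patient record")))
  }

  if (nrow(ev) > 0) {
    per <- dplyr::summarise(dplyr::group_by(ev, .data$patient_id),
                            first_event = min(.data$date),
                            last_event = max(.data$date), .groups = "drop")
    per <- dplyr::inner_join(per, pat, by = "patient_id")
    i <- !is.na(per$death_date) & per$last_event > per$death_date
    if (any(i)) bad <- c(bad, list(viol(per$patient_id[i], "event after death")))
    i <- per$first_event < per$birth_date
    if (any(i)) bad <- c(bad, list(viol(per$patient_id[i], "event before birth")))
  }

  if (length(bad) == 0) {
    return(tibble::tibble(patient_id = character(), rule = character()))
  }
  dplyr::distinct(dplyr::arrange(dplyr::bind_rows(bad), .data$patient_id, .data$rule))
}

#' Read an event-log file
#'
#' Parses the tab-separated event-log format: lines starting `#` are header
#' comments; `E` rows carry events
#' (`E<TAB>patient_id<TAB>date<TAB>category<TAB>code[<TAB>encounter_type]`)
#' and `P` rows carry demographics
#' (`P<TAB>patient_id<TAB>birth_date<TAB>gender<TAB>race<TAB>ethnicity<TAB>death_date_or_NA`).
#'
#' @param path Path to an event-log file (UTF-8).
#' @return An [ehr_population()] with patients ordered by `patient_id` and
#'   events by date; the result is independent of the row order in the file.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(ehr_population(
      tibble::tibble(patient_id = character(), birth_date = integer(),
                     gender = character(), race = character(),
                     ethnicity = character(), death_date = integer()),
      tibble::tibble(patient_id = character(), date = integer(),
                     category = character(), code = character(),
                     encounter_type = character())
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, "", 1L)
  nfield <- lengths(parts)

  parse_fail <- function(i, why) {
    stop(sprintf("parse error at line %d: %s", lineno[i], why), call. = FALSE)
  }
  as_int <- function(x, i, what) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) & !(x == "NA" & what == "death_date"))
    if (length(bad) > 0) parse_fail(i[bad[1]], paste0("non-integer ", what, " '", x[bad[1]], "'"))
    v
  }

  bad <- which(!tag %in% c("E", "P"))
  if (length(bad) > 0) parse_fail(bad[1], paste0("unknown record tag '", tag[bad[1]], "'"))

  ei <- which(tag == "E")
  pi_ <- which(tag == "P")
  bad <- ei[!nfield[ei] %in% c(5L, 6L)]
  if (length(bad) > 0) parse_fail(bad[1], "event row must have 5 or 6 fields")
  bad <- pi_[nfield[pi_] != 7L]
  if (length(bad) > 0) parse_fail(bad[1], "patient row must have 7 fields")

  field <- function(idx, k) vapply(parts[idx], function(p) if (length(p) >= k) p[[k]] else NA_character_, "")

  events <- tibble::tibble(
    patient_id = field(ei, 2L),
    date = as_int(field(ei, 3L), ei, "date"),
    category = field(ei, 4L),
    code = field(ei, 5L),
    encounter_type = field(ei, 6L)
  )
  bad <- which(!events$category %in% CODE_CATEGORIES)
  if (length(bad) > 0) parse_fail(ei[bad[1]], paste0("unknown category '", events$category[bad[1]], "'"))

  patients <- tibble::tibble(
    patient_id = field(pi_, 2L),
    birth_date = as_int(field(pi_, 3L), pi_, "birth_date"),
    gender = field(pi_, 4L),
    race = field(pi_, 5L),
    ethnicity = field(pi_, 6L),
    death_raw = field(pi_, 7L)
  )
  patients$death_date <- ifelse(patients$death_raw == "NA", NA_integer_,
                                as_int(patients$death_raw, pi_, "death_date"))
  patients$death_raw <- NULL

  pop <- ehr_population(patients, events, validate = FALSE)
  v <- validate_population(pop)
  after_death <- v[v$rule == "event after death", ]
  if (nrow(after_death) > 0) {
    stop("validation error: patient ", after_death$patient_id[1],
         ": event after death_date", call. = FALSE)
  }
  if (nrow(v) > 0) {
    stop("validation error: patient ", v$patient_id[1], ": ", v$rule[1], call. = FALSE)
  }
  pop
}

#' Write an event-log file
#'
#' Inverse of [read_event_log()]: writes one `P` row per patient and one `E`
#' row per event, preceded by a `#` header line. Reading the file back
#' reproduces the population field-for-field.
#'
#' @param population An [ehr_population()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(population, path) {
  pat <- population$patients
  ev <- population$events
  p_lines <- sprintf("P\t%s\t%d\t%s\t%s\t%s\t%s",
                     pat$patient_id, pat$birth_date, pat$gender, pat$race,
                     pat$ethnicity,
                     ifelse(is.na(pat$death_date), "NA", as.character(pat$death_date)))
  is_enc <- ev$category == "ENCOUNTER"
  e_lines <- ifelse(
    is_enc,
    sprintf("E\t%s\t%d\t%s\t%s\t%s", ev$patient_id, ev$date, ev$category,
            ev$code, ev$encounter_type),
    sprintf("E\t%s\t%d\t%s\t%s", ev$patient_id, ev$date, ev$category, ev$code)
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# palliascreen event log v1", p_lines, e_lines), con)
  invisible(path)
}

# Age in completed years at a reference date.
age_years <- function(birth_date, at_date) {
  as.integer(floor((at_date - birth_date) / 365.25))
}
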