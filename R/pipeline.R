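# End-to-end orchestration: simulate -> build-cohort -> featurize -> train
# -> evaluate (-> explain / screen). Every stage logs counts; every source of
# randomness flows from the seeds recorded in the config.

#' Configure an end-to-end pipeline run
#'
#' @param out_dir Directory for artifacts (created if missing).
#' @param sim A [sim_config()] describing the population to simulate; omit
#'   (`NULL`) to read an existing event log from `event_log_path`.
#' @param event_log_path Optional path to an input event log (used when `sim`
#'   is `NULL`; also where the simulated log is written).
#' @param split_ratios Train/validation/test weights, default `c(8, 1, 1)`.
#' @param split_seed Seed for the cohort split.
#' @param min_patient_support Vocabulary pruning threshold, default 100.
#' @param model Partial [model_config()] arguments as a list (everything but
#'   `input_dim`, which is filled from the vocabulary).
#' @param precision_targets Precision levels for recall-at-precision.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            event_log_path = NULL,
                            split_ratios = c(8, 1, 1),
                            split_seed = 1L,
                            min_patient_support = 100L,
                            model = list(),
                            precision_targets = 0.9) {
  structure(list(out_dir = out_dir, sim = sim,
                 event_log_path = event_log_path,
                 split_ratios = split_ratios,
                 split_seed = as.integer(split_seed),
                 min_patient_support = min_patient_support,
                 model = model,
                 precision_targets = precision_targets),
            class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full screening pipeline
#'
#' Executes every stage in order and writes all artifacts under
#' `config$out_dir`: the event log, the cohort instance table, the
#' vocabulary, train/validation/test feature matrices, the trained model,
#' the evaluation report (JSON) and a run manifest recording seeds and
#' per-stage counts. Rerunning with the same config reproduces the same
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the population, cohort, vocabulary,
#'   matrices, model, test-set `evaluation_report`, and the stage-count
#'   summary.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$sim)) {
    population <- generate_population(config$sim)
    log_stage("simulate", "%d patients, %d events, %d deceased",
              nrow(population$patients), nrow(population$events),
              sum(!is.na(population$patients$death_date)))
    write_event_log(population, config$event_log_path %||% path("events.tsv"))
  } else {
    if (is.null(config$event_log_path)) {
      stop("run_all: either `sim` or `event_log_path` is required", call. = FALSE)
    }
    population <- read_event_log(config$event_log_path)
    log_stage("read", "%d patients, %d events", nrow(population$patients),
              nrow(population$events))
  }

  cohort <- build_cohort(population)
  if (nrow(cohort$instances) + nrow(cohort$exclusions) !=
      nrow(population$patients)) {
    stop("stage error in build-cohort: patients not conserved", call. = FALSE)
  }
  log_stage("build-cohort", "%d instances (%d positive, %d admitted), %d excluded",
            nrow(cohort$instances), sum(cohort$instances$label),
            sum(cohort$instances$admitted), nrow(cohort$exclusions))
  cohort <- split_cohort(cohort, ratios = config$split_ratios,
                         seed = config$split_seed)
  write_cohort(cohort, path("cohort.tsv"))

  train <- cohort_subset(cohort, split = "train")
  validation <- cohort_subset(cohort, split = "validation")
  test <- cohort_subset(cohort, split = "test")
  vocab <- build_vocabulary(train, config$min_patient_support)
  log_stage("featurize", "%d features kept (support > %d) from training split of %d",
            nrow(vocab), config$min_patient_support, nrow(train$instances))
  write_vocabulary(vocab, path("vocabulary.tsv"))
  fm <- list(train = vectorize(train, vocab),
             validation = vectorize(validation, vocab),
             test = vectorize(test, vocab))
  for (s in names(fm)) write_feature_matrix(fm[[s]], path(paste0(s, ".mtx")))

  margs <- config$model
  margs$input_dim <- nrow(vocab)
  mcfg <- do.call(model_config, margs)
  model <- train_mortality_model(fm$train, fm$validation, mcfg)
  log_stage("train", "%d snapshots, best validation AP %.4f at iteration %d",
            nrow(model$ap_history), max(model$ap_history$validation_ap),
            model$selected_iteration)
  save_model(model, path("model.rds"))

  scores <- predict_probability(model, fm$test)
  report <- evaluate_predictions(scores, fm$test$labels,
                                 precision_targets = config$precision_targets)
  log_stage("evaluate", "test AP %.4f, AUROC %.4f, Brier %.4f",
            report$ap, report$auroc, report$brier)
  write_evaluation_report(report, path("evaluation.json"))

  summary <- list(
    n_patients = nrow(population$patients),
    n_instances = nrow(cohort$instances),
    n_excluded = nrow(cohort$exclusions),
    n_positive = sum(cohort$instances$label),
    n_admitted = sum(cohort$instances$admitted),
    split_sizes = table(cohort$instances$split),
    n_features = nrow(vocab),
    n_snapshots = nrow(model$ap_history),
    selected_iteration = model$selected_iteration,
    best_validation_ap = max(model$ap_history$validation_ap),
    seeds = list(sim = if (!is.null(config$sim)) config$sim$seed,
                 split = config$split_seed,
                 model = mcfg$seed)
  )
  jsonlite::write_json(summary, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(population = population, cohort = cohort, vocabulary = vocab,
                 matrices = fm, model = model, report = report,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort
#'
#' The instance table goes to `<path>` as TSV; the censored event log and the
#' included patients' demographics go to `<path>.events` in the event-log
#' format.
#'
#' @param cohort A `mortality_cohort`.
#' @param path Instance-table path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort$instances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pop <- ehr_population(cohort$patients, cohort$events, validate = FALSE)
  write_event_log(pop, paste0(path, ".events"))
  utils::write.table(cohort$exclusions, paste0(path, ".exclusions"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  inst <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                              colClasses = c(patient_id = "character")))
  pop <- read_event_log(paste0(path, ".events"))
  excl_path <- paste0(path, ".exclusions")
  exclusions <- if (file.exists(excl_path)) {
    tibble::as_tibble(utils::read.table(excl_path, sep = "\t", header = TRUE,
                                        colClasses = c(patient_id = "character")))
  } else {
    tibble::tibble(patient_id = character(), reason = character())
  }
  structure(list(instances = inst, events = pop$events,
                 patients = pop$patients, exclusions = exclusions),
            class = "mortality_cohort")
}

#' Screen currently admitted patients
#'
#' The deployment-time variant of cohort construction: no labels are
#' involved. Every patient who is inside an inpatient admission on
#' `as_of_date` (an INPATIENT encounter day on that date), is not recorded
#' dead by then, and has at least 365 days of history since their first
#' encounter is featurized with `as_of_date` as the prediction date (record
#' censored there) and scored.
#'
#' @param population An [ehr_population()].
#' @param model A trained `mortality_model`.
#' @param vocabulary The `feature_vocabulary` the model was trained on.
#' @param as_of_date Integer day index of the screening run.
#' @return Tibble `patient_id`, `probability`, sorted descending by
#'   probability.
#' @export
run_screen <- function(population, model, vocabulary, as_of_date) {
  if (is.null(model)) stop("run_screen requires a trained model", call. = FALSE)
  inpat <- dplyr::filter(population$events, .data$category == "ENCOUNTER",
                         .data$encounter_type == "INPATIENT",
                         .data$date == as_of_date)
  enc <- dplyr::filter(population$events, .data$category == "ENCOUNTER")
  first_enc <- dplyr::summarise(dplyr::group_by(enc, .data$patient_id),
                                first_encounter = min(.data$date),
                                .groups = "drop")
  eligible <- dplyr::inner_join(dplyr::distinct(inpat, .data$patient_id),
                                first_enc, by = "patient_id")
  eligible <- dplyr::inner_join(eligible, population$patients, by = "patient_id")
  eligible <- dplyr::filter(
    eligible,
    as_of_date - .data$first_encounter >= DAYS_12M,
    is.na(.data$death_date) | .data$death_date > as_of_date
  )
  if (nrow(eligible) == 0) {
    return(tibble::tibble(patient_id = character(), probability = double()))
  }

  inst <- tibble::tibble(patient_id = sort(eligible$patient_id),
                         prediction_date = as.integer(as_of_date),
                         label = 0L, admitted = TRUE,
                         censor_length = NA_integer_)
  ev <- dplyr::semi_join(population$events, inst, by = "patient_id")
  ev <- dplyr::filter(ev, .data$date <= as_of_date)
  screen_cohort <- structure(
    list(instances = inst, events = ev,
         patients = dplyr::semi_join(population$patients, inst, by = "patient_id"),
         exclusions = tibble::tibble(patient_id = character(), reason = character())),
    class = "mortality_cohort"
  )
  fm <- vectorize(screen_cohort, vocabulary)
  out <- tibble::tibble(patient_id = fm$row_ids,
                        probability = predict_probability(model, fm))
  dplyr::arrange(out, dplyr::desc(.data$probability), .data$patient_id)
}
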