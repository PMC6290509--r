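# Counterfactual explanation of a single prediction.
#
# The influence of a code on a patient's score is the drop in log-probability
# when every occurrence of that code is removed from the record and ALL
# features — slice counts and the per-category summary statistics — are
# recomputed from the ablated event list. Demographics get dedicated
# counterfactuals: age is zeroed and gender is swapped to the opposite sex.
# Only factors with a positive drop are reported, top 5 per display category.

CATEGORY_DISPLAY <- c(ICD9 = "Diagnostic", CPT = "Procedural",
                      RXCUI = "Medication", ENCOUNTER = "Encounter",
                      DEMO = "Demographic")
LOG_P_CLIP <- 1e-12

STAT_DISPLAY <- c(unique_count = "Code_Type_Count",
                  total_count = "Code_Count",
                  max_per_day = "Max_Codes_per_Day",
                  min_nonzero_per_day = "Min_Codes_per_Day",
                  range_per_day = "Range_Codes_per_Day",
                  mean_per_day = "Mean_Codes_per_Day",
                  var_per_day = "Var_Codes_per_Day")

#' Remove all occurrences of a code from an instance
#'
#' Returns a copy of the instance with every event matching `(code,
#' category)` dropped; the input is never modified. Downstream featurization
#' recomputes slice counts and summary statistics from the remaining events.
#'
#' @param instance A single-instance `mortality_cohort`
#'   (see [cohort_instance()]).
#' @param code Code token to remove.
#' @param category Its category.
#' @return A single-instance `mortality_cohort`.
#' @export
ablate_code <- function(instance, code, category) {
  inst <- as_instance_cohort(instance)
  inst$events <- dplyr::filter(
    inst$events, !(.data$code == !!code & .data$category == !!category))
  inst
}

instance_row <- function(instance, vocabulary) {
  vectorize(instance, vocabulary)$matrix
}

clipped_log_p <- function(model, row) {
  p <- predict_probability(model, row)
  log(pmin(pmax(p, LOG_P_CLIP), 1 - LOG_P_CLIP))
}

#' Influence of a code on a prediction
#'
#' `log p(original) - log p(ablated)`: positive when removing the code lowers
#' the predicted death probability, i.e. the code contributed risk. Exactly 0
#' when the ablation leaves the feature vector unchanged (in particular for
#' codes absent from the observation window).
#'
#' @param model A `mortality_model`.
#' @param vocabulary The `feature_vocabulary` the model was trained on.
#' @param instance A single-instance `mortality_cohort`.
#' @param code,category The code to ablate.
#' @return Finite numeric influence (natural log scale).
#' @export
code_influence <- function(model, vocabulary, instance, code, category) {
  inst <- as_instance_cohort(instance)
  x0 <- instance_row(inst, vocabulary)
  x1 <- instance_row(ablate_code(inst, code, category), vocabulary)
  if (isTRUE(all(x0 == x1))) return(0)
  clipped_log_p(model, x0) - clipped_log_p(model, x1)
}

# perturb a dense feature row in place: zero age / swap gender one-hot
perturb_demo <- function(x, vocabulary, what, gender = NULL) {
  x <- x
  if (what == "age") {
    j <- match("DEMO|age", vocabulary$feature)
    if (!is.na(j)) x[1, j] <- 0
  } else if (what == "gender" && !is.null(gender) && gender %in% c("MALE", "FEMALE")) {
    opp <- if (gender == "MALE") "FEMALE" else "MALE"
    j_from <- match(serialize_feature("DEMO", "gender", gender), vocabulary$feature)
    j_to <- match(serialize_feature("DEMO", "gender", opp), vocabulary$feature)
    if (!is.na(j_from)) x[1, j_from] <- 0
    if (!is.na(j_to)) x[1, j_to] <- 1
  }
  x
}

#' Demographic counterfactual influences
#'
#' Age: the drop in log-probability when the age feature is set to 0.
#' Gender: the drop when the gender one-hot is swapped to the opposite sex
#' (patients recorded as `OTHER` are left unperturbed, influence 0). Race and
#' ethnicity are not perturbed.
#'
#' @inheritParams code_influence
#' @return Tibble `code`, `value`, `influence`, `description` with rows
#'   `Age` and `Gender`.
#' @export
demographic_influences <- function(model, vocabulary, instance) {
  inst <- as_instance_cohort(instance)
  x0 <- instance_row(inst, vocabulary)
  lp0 <- clipped_log_p(model, x0)
  pd <- inst$instances$prediction_date[[1]]
  age <- age_years(inst$patients$birth_date[[1]], pd)
  gender <- inst$patients$gender[[1]]

  x_age <- perturb_demo(x0, vocabulary, "age")
  inf_age <- if (isTRUE(all(x_age == x0))) 0 else lp0 - clipped_log_p(model, x_age)
  x_g <- perturb_demo(x0, vocabulary, "gender", gender = gender)
  inf_g <- if (isTRUE(all(x_g == x0))) 0 else lp0 - clipped_log_p(model, x_g)

  tibble::tibble(
    code = c("Age", "Gender"),
    value = c(as.character(age), gender),
    influence = c(inf_age, inf_g),
    description = c("Age of patient in years at prediction time, zeroed",
                    "Recorded gender, swapped to the opposite sex")
  )
}

#' Explain one prediction by counterfactual ablation
#'
#' Scores the influence of every distinct code observed in the instance's
#' window plus the two demographic counterfactuals; optionally also ablates
#' each summary-statistic feature directly (setting it to 0). Factors with a
#' non-positive influence are dropped; the rest are ranked descending within
#' display category (ties broken lexicographically by code) and truncated to
#' `top_k`.
#'
#' @inheritParams code_influence
#' @param top_k Factors kept per category, default 5.
#' @param include_stat_ablation Also report summary-statistic features as
#'   standalone factors by zeroing them one at a time. Default `FALSE`.
#' @return An `explanation_report`: `patient_id`, `probability_score`, and a
#'   `factors` tibble (`factor_category`, `code`, `value`, `influence`,
#'   `description`).
#' @export
explain_prediction <- function(model, vocabulary, instance, top_k = 5L,
                               include_stat_ablation = FALSE) {
  inst <- as_instance_cohort(instance)
  x0 <- instance_row(inst, vocabulary)
  p0 <- predict_probability(model, x0)
  lp0 <- log(pmin(pmax(p0, LOG_P_CLIP), 1 - LOG_P_CLIP))
  pd <- inst$instances$prediction_date[[1]]

  # distinct codes observed in the window, with window counts as the
  # reported factor value
  ev <- dplyr::mutate(inst$events, offset = pd - .data$date)
  ev <- dplyr::filter(ev, .data$offset >= 0, .data$offset < 365)
  codes <- dplyr::count(ev, .data$category, .data$code, name = "window_count")

  code_rows <- purrr::pmap_dfr(codes, function(category, code, window_count) {
    x1 <- instance_row(ablate_code(inst, code, category), vocabulary)
    inf <- if (isTRUE(all(x1 == x0))) 0 else lp0 - clipped_log_p(model, x1)
    tibble::tibble(
      factor_category = CATEGORY_DISPLAY[[category]],
      code = code,
      value = as.character(window_count),
      influence = inf,
      description = if (category == "ENCOUNTER") {
        paste0("Number of ", code, " encounter days in the window")
      } else {
        paste0(category, " code ", code, " (occurrences in the window)")
      }
    )
  })

  stat_rows <- NULL
  if (include_stat_ablation) {
    stats_present <- vocabulary$feature[vocabulary$kind == "STAT"]
    js <- match(stats_present, vocabulary$feature)
    nonzero <- which(x0[1, js] != 0)
    stat_rows <- purrr::map_dfr(nonzero, function(ii) {
      j <- js[ii]
      x1 <- x0
      x1[1, j] <- 0
      parsed <- parse_feature_names(stats_present[ii])
      tibble::tibble(
        factor_category = CATEGORY_DISPLAY[[parsed$category]],
        code = STAT_DISPLAY[[parsed$stat]],
        value = format(x0[1, j]),
        influence = lp0 - clipped_log_p(model, x1),
        description = paste0("Summary statistic (", parsed$stat, ", ",
                             parsed$category, ")")
      )
    })
  }

  demo_rows <- demographic_influences(model, vocabulary, inst)
  demo_rows <- dplyr::mutate(demo_rows, factor_category = "Demographic")

  factors <- dplyr::bind_rows(code_rows, stat_rows, demo_rows)
  factors <- dplyr::filter(factors, .data$influence > 0)
  factors <- dplyr::arrange(factors, .data$factor_category,
                            dplyr::desc(.data$influence), .data$code)
  factors <- dplyr::slice_head(
    dplyr::group_by(factors, .data$factor_category), n = top_k)
  factors <- dplyr::ungroup(factors)
  factors$factor_category <- factor(
    factors$factor_category, levels = unname(CATEGORY_DISPLAY))
  factors <- dplyr::arrange(factors, .data$factor_category,
                            dplyr::desc(.data$influence), .data$code)

  structure(list(patient_id = inst$instances$patient_id[[1]],
                 probability_score = unname(p0),
                 factors = factors),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(format_explanation(x), sep = "\n")
  invisible(x)
}

#' Render an explanation as an aligned text table
#'
#' @param report An `explanation_report`.
#' @return Character vector of lines (Factors / Code / Value / Influence /
#'   Description columns, one section per factor category).
#' @export
format_explanation <- function(report) {
  f <- report$factors
  lines <- c(sprintf("Patient %s", report$patient_id),
             sprintf("Probability score %.3f", report$probability_score))
  fmt <- function(a, b, c_, d) sprintf("%-22s %-10s %10s  %s", a, b, c_, d)
  lines <- c(lines, fmt("Code", "Value", "Influence", "Description"))
  for (cat_ in levels(f$factor_category)) {
    rows <- f[f$factor_category == cat_, ]
    lines <- c(lines, paste0("Top ", cat_, " factors"))
    if (nrow(rows) == 0) next
    lines <- c(lines, fmt(rows$code, rows$value,
                          sprintf("%.4f", rows$influence), rows$description))
  }
  c(lines, "Only factors that contributed to a drop in probability score are reported")
}

#' @export
tidy.explanation_report <- function(x, ...) {
  dplyr::mutate(x$factors, patient_id = x$patient_id,
                probability_score = x$probability_score)
}

#' Serialize an explanation report
#'
#' Writes the report as JSON to `path` and, when `text_path` is given, as an
#' aligned text table.
#'
#' @param report An `explanation_report`.
#' @param path JSON output path.
#' @param text_path Optional text-table output path.
#' @return `path`, invisibly.
#' @export
write_explanation <- function(report, path, text_path = NULL) {
  out <- list(patient_id = report$patient_id,
              probability_score = report$probability_score,
              factors = dplyr::mutate(report$factors,
                                      factor_category = as.character(.data$factor_category)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(text_path)) writeLines(format_explanation(report), text_path)
  invisible(path)
}
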