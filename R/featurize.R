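# Featurization of censored instances.
#
# The observation window is the 365 days up to and including the prediction
# date (PD). It is partitioned into four recency-weighted slices, half-open
# (start, end] so an event on PD counts and every event falls in exactly one
# slice:
#   slice 1 (PD-30,  PD]      30 days
#   slice 2 (PD-90,  PD-30]   60 days
#   slice 3 (PD-180, PD-90]   90 days
#   slice 4 (PD-365, PD-180] 185 days
#
# Three feature families, named by a lossless serialized token:
#   SLICE|<category>|<code>|<slice>   per-code occurrence count in a slice
#   STAT|<category>|<stat>            per-category window summary statistic
#   DEMO|age, DEMO|<field>|<level>    demographics (age numeric, rest one-hot)

SLICE_BREAKS <- c(0L, 30L, 90L, 180L, 365L)
STAT_KINDS <- c("unique_count", "total_count", "max_per_day",
                "min_nonzero_per_day", "range_per_day", "mean_per_day",
                "var_per_day")

#' Observation window slices for a prediction date
#'
#' @param prediction_date Integer day index (PD).
#' @return Tibble with columns `slice`, `start`, `end`, `duration`; intervals
#'   are half-open `(start, end]`. Durations are 30, 60, 90, 185 days and sum
#'   to the 365-day window.
#' @export
slice_intervals <- function(prediction_date) {
  tibble::tibble(
    slice = 1:4,
    start = as.integer(prediction_date) - SLICE_BREAKS[2:5],
    end = as.integer(prediction_date) - SLICE_BREAKS[1:4],
    duration = diff(SLICE_BREAKS)
  )
}

# slice index for an event `offset = PD - date` days before PD; NA outside
# the window. Offset 0 (event on PD) -> slice 1; offset 30 -> slice 2.
slice_of_offset <- function(offset) {
  idx <- findInterval(offset, SLICE_BREAKS, left.open = FALSE)
  idx[offset < 0L | offset >= 365L] <- NA_integer_
  idx
}

serialize_feature <- function(...) paste(..., sep = "|")

#' Parse serialized feature names
#'
#' @param feature Character vector of feature tokens.
#' @return Tibble with columns `feature`, `kind` (`SLICE`/`STAT`/`DEMO`),
#'   `category`, `code`, `slice`, `stat`, `field`, `level` (unused parts `NA`).
#' @export
parse_feature_names <- function(feature) {
  parts <- strsplit(feature, "|", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[[k]] else NA_character_, "")
  tibble::tibble(
    feature = feature,
    kind = kind,
    category = ifelse(kind %in% c("SLICE", "STAT"), get(2L), NA_character_),
    code = ifelse(kind == "SLICE", get(3L), NA_character_),
    slice = ifelse(kind == "SLICE", suppressWarnings(as.integer(get(4L))), NA_integer_),
    stat = ifelse(kind == "STAT", get(3L), NA_character_),
    field = ifelse(kind == "DEMO", get(2L), NA_character_),
    level = ifelse(kind == "DEMO", get(3L), NA_character_)
  )
}

# Long feature table for every instance of a cohort: one row per
# (patient_id, feature) with a non-zero (or stat-defined) value. The cohort's
# events are already censored; the window filter keeps offsets in [0, 365).
compute_features <- function(cohort) {
  inst <- cohort$instances
  ev <- dplyr::inner_join(cohort$events,
                          dplyr::select(inst, "patient_id", "prediction_date"),
                          by = "patient_id")
  ev <- dplyr::mutate(ev, offset = .data$prediction_date - .data$date,
                      slice = slice_of_offset(.data$offset))
  ev <- dplyr::filter(ev, !is.na(.data$slice))
  if (nrow(ev) == 0) {
    return(demo_feature_rows(cohort))
  }

  slice_feats <- dplyr::count(ev, .data$patient_id, .data$category, .data$code,
                              .data$slice, name = "value")
  slice_feats <- dplyr::transmute(
    slice_feats, .data$patient_id,
    feature = serialize_feature("SLICE", .data$category, .data$code, .data$slice),
    value = as.numeric(.data$value)
  )

  # daily tallies over active days only (days with >= 1 event of the category)
  daily <- dplyr::count(ev, .data$patient_id, .data$category, .data$date,
                        name = "n_day")
  per_cat <- dplyr::summarise(
    dplyr::group_by(ev, .data$patient_id, .data$category),
    unique_count = dplyr::n_distinct(.data$code),
    total_count = dplyr::n(), .groups = "drop"
  )
  daily_stats <- dplyr::summarise(
    dplyr::group_by(daily, .data$patient_id, .data$category),
    max_per_day = max(.data$n_day),
    min_nonzero_per_day = min(.data$n_day),
    mean_per_day = mean(.data$n_day),
    var_per_day = mean((.data$n_day - mean(.data$n_day))^2),
    .groups = "drop"
  )
  stats_wide <- dplyr::inner_join(per_cat, daily_stats,
                                  by = c("patient_id", "category"))
  stats_wide <- dplyr::mutate(stats_wide,
                              range_per_day = .data$max_per_day - .data$min_nonzero_per_day)
  stat_feats <- tidyr::pivot_longer(stats_wide, dplyr::all_of(STAT_KINDS),
                                    names_to = "stat", values_to = "value")
  stat_feats <- dplyr::transmute(
    stat_feats, .data$patient_id,
    feature = serialize_feature("STAT", .data$category, .data$stat),
    value = as.numeric(.data$value)
  )

  demo_feats <- demo_feature_rows(cohort)

  dplyr::bind_rows(slice_feats, stat_feats, demo_feats)
}

demo_feature_rows <- function(cohort) {
  demo <- dplyr::inner_join(cohort$patients,
                            dplyr::select(cohort$instances, "patient_id",
                                          "prediction_date"),
                            by = "patient_id")
  dplyr::bind_rows(
    dplyr::transmute(demo, .data$patient_id, feature = "DEMO|age",
                     value = as.numeric(age_years(.data$birth_date, .data$prediction_date))),
    dplyr::transmute(demo, .data$patient_id,
                     feature = serialize_feature("DEMO", "gender", .data$gender),
                     value = 1),
    dplyr::transmute(demo, .data$patient_id,
                     feature = serialize_feature("DEMO", "race", .data$race),
                     value = 1),
    dplyr::transmute(demo, .data$patient_id,
                     feature = serialize_feature("DEMO", "ethnicity", .data$ethnicity),
                     value = 1)
  )
}

# Single-instance cohort wrapper for the per-instance operations.
as_instance_cohort <- function(instance) {
  if (inherits(instance, "mortality_cohort")) {
    stopifnot(nrow(instance$instances) == 1)
    return(instance)
  }
  stop("`instance` must be a single-instance mortality_cohort (see cohort_instance())",
       call. = FALSE)
}

#' Extract one instance from a cohort
#'
#' @param cohort A `mortality_cohort`.
#' @param patient_id Patient id of the instance to extract.
#' @return A single-instance `mortality_cohort`.
#' @export
cohort_instance <- function(cohort, patient_id) {
  out <- cohort_subset(cohort, patient_ids = patient_id)
  if (nrow(out$instances) != 1) {
    stop("patient ", patient_id, " is not in the cohort", call. = FALSE)
  }
  out
}

#' Per-slice code counts of one instance
#'
#' @param instance A single-instance `mortality_cohort` ([cohort_instance()]).
#' @return Tibble `category`, `code`, `slice`, `count` for every code with at
#'   least one occurrence in the observation window; zero counts are omitted.
#' @export
slice_code_counts <- function(instance) {
  inst <- as_instance_cohort(instance)
  f <- compute_features(inst)
  f <- dplyr::inner_join(f, parse_feature_names(unique(f$feature)), by = "feature")
  f <- dplyr::filter(f, .data$kind == "SLICE")
  dplyr::arrange(
    dplyr::transmute(f, .data$category, .data$code, .data$slice,
                     count = .data$value),
    .data$category, .data$code, .data$slice
  )
}

#' Window summary statistics of one instance for a category
#'
#' Over the full 365-day window: distinct and total code counts, and the
#' maximum, minimum, range, mean and (population) variance of the daily code
#' tally computed over active days — days with at least one event of the
#' category. Returns an empty tibble when the category has no events in the
#' window.
#'
#' @param instance A single-instance `mortality_cohort`.
#' @param category One of [code_categories()].
#' @return Tibble `stat`, `value`.
#' @export
category_summary_stats <- function(instance, category) {
  stopifnot(category %in% CODE_CATEGORIES)
  inst <- as_instance_cohort(instance)
  f <- compute_features(inst)
  f <- dplyr::inner_join(f, parse_feature_names(unique(f$feature)), by = "feature")
  f <- dplyr::filter(f, .data$kind == "STAT", .data$category == !!category)
  out <- dplyr::transmute(f, stat = .data$stat, value = .data$value)
  out[match(intersect(STAT_KINDS, out$stat), out$stat), ]
}

#' Demographic features of one instance
#'
#' Age in completed years at the prediction date (numeric) plus one-hot
#' gender, race and ethnicity indicators.
#'
#' @param instance A single-instance `mortality_cohort`.
#' @return Named numeric vector keyed by serialized feature name.
#' @export
demographic_features <- function(instance) {
  inst <- as_instance_cohort(instance)
  f <- compute_features(inst)
  f <- f[startsWith(f$feature, "DEMO|"), ]
  setNames(f$value, f$feature)
}

#' Build a pruned feature vocabulary from training instances
#'
#' Candidate features are the union of all features emitted by the training
#' instances. SLICE and STAT features supported by `min_patient_support` or
#' fewer training patients (patients with a non-zero value) are pruned;
#' demographic features are always retained. Ordering is lexicographic by
#' serialized name, so identical training sets give identical vocabularies.
#'
#' @param training_cohort A `mortality_cohort` holding the training instances
#'   only (e.g. `cohort_subset(cohort, split = "train")`).
#' @param min_patient_support Support threshold; a feature must occur in more
#'   than this many training patients to be kept. Default 100.
#' @return A `feature_vocabulary`: tibble `feature`, `kind`, `support`,
#'   `position` (0-based, contiguous).
#' @export
build_vocabulary <- function(training_cohort, min_patient_support = 100L) {
  stopifnot(inherits(training_cohort, "mortality_cohort"))
  if (nrow(training_cohort$instances) == 0) {
    stop("cannot build a vocabulary from an empty training set", call. = FALSE)
  }
  f <- compute_features(training_cohort)
  f <- dplyr::filter(f, .data$value != 0)
  support <- dplyr::summarise(dplyr::group_by(f, .data$feature),
                              support = dplyr::n_distinct(.data$patient_id),
                              .groups = "drop")
  support$kind <- vapply(strsplit(support$feature, "|", fixed = TRUE), `[[`, "", 1L)
  kept <- dplyr::filter(support,
                        .data$kind == "DEMO" | .data$support > min_patient_support)
  kept <- dplyr::arrange(kept, .data$feature)
  kept$position <- seq_len(nrow(kept)) - 1L
  structure(kept[, c("feature", "kind", "support", "position")],
            class = c("feature_vocabulary", class(kept)))
}

#' Vectorize cohort instances against a vocabulary
#'
#' One sparse row per instance; features outside the vocabulary are dropped,
#' vocabulary features absent from an instance are 0. Row order follows the
#' instance table.
#'
#' @param cohort A `mortality_cohort`.
#' @param vocabulary A `feature_vocabulary` from [build_vocabulary()].
#' @return A `feature_matrix`: list with `matrix` (dgCMatrix, dimnames =
#'   patient ids x feature names), `labels` (0/1 integer) and `row_ids`.
#' @export
vectorize <- function(cohort, vocabulary) {
  stopifnot(inherits(cohort, "mortality_cohort"),
            inherits(vocabulary, "feature_vocabulary"))
  inst <- cohort$instances
  f <- compute_features(cohort)
  f <- dplyr::filter(f, .data$value != 0)
  f <- dplyr::inner_join(f, vocabulary[, c("feature", "position")], by = "feature")
  row_of <- match(f$patient_id, inst$patient_id)
  m <- Matrix::sparseMatrix(
    i = row_of, j = f$position + 1L, x = f$value,
    dims = c(nrow(inst), nrow(vocabulary)),
    dimnames = list(inst$patient_id, vocabulary$feature)
  )
  structure(list(matrix = m, labels = inst$label, row_ids = inst$patient_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  nz <- Matrix::nnzero(x$matrix)
  cat("<feature_matrix> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (", sum(x$labels), " positive; ",
      sprintf("%.2f%% sparse", 100 * (1 - nz / max(1, prod(dim(x$matrix))))),
      ", mean ", sprintf("%.1f", nz / max(1, nrow(x$matrix))),
      " non-zeros/row)\n", sep = "")
  invisible(x)
}

#' Write / read a feature vocabulary as text
#'
#' One tab-separated `feature<TAB>support` line per feature, in position
#' order.
#'
#' @param vocabulary A `feature_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   returns the `feature_vocabulary`.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(c("# palliascreen vocabulary v1",
               sprintf("%s\t%d", vocabulary$feature, vocabulary$support)), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble::tibble(
    feature = vapply(parts, `[[`, "", 1L),
    support = as.integer(vapply(parts, `[[`, "", 2L))
  )
  out$kind <- vapply(strsplit(out$feature, "|", fixed = TRUE), `[[`, "", 1L)
  out$position <- seq_len(nrow(out)) - 1L
  structure(out[, c("feature", "kind", "support", "position")],
            class = c("feature_vocabulary", class(out)))
}

#' Write / read a feature matrix (MatrixMarket + sidecar)
#'
#' The sparse matrix goes to `<path>` in MatrixMarket coordinate format; row
#' ids and labels go to `<path>.rows.tsv`; column names to `<path>.cols.tsv`.
#'
#' @param fm A `feature_matrix`.
#' @param path Base path for the `.mtx` file.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  Matrix::writeMM(fm$matrix, path)
  writeLines(sprintf("%s\t%d", fm$row_ids, fm$labels),
             paste0(path, ".rows.tsv"))
  writeLines(colnames(fm$matrix), paste0(path, ".cols.tsv"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  rows <- strsplit(readLines(paste0(path, ".rows.tsv")), "\t", fixed = TRUE)
  cols <- readLines(paste0(path, ".cols.tsv"))
  row_ids <- vapply(rows, `[[`, "", 1L)
  labels <- as.integer(vapply(rows, `[[`, "", 2L))
  dimnames(m) <- list(row_ids, cols)
  structure(list(matrix = m, labels = labels, row_ids = row_ids),
            class = "feature_matrix")
}
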