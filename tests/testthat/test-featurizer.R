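test_that("slice intervals reproduce the 30/60/90/185-day partition", {
  s <- slice_intervals(2000L)
  expect_equal(s$start, c(1970L, 1910L, 1820L, 1635L))
  expect_equal(s$end, c(2000L, 1970L, 1910L, 1820L))
  expect_equal(s$duration, c(30L, 60L, 90L, 185L))
  expect_equal(sum(s$duration), 365L)
  # half-open (start, end]: PD-30 belongs to slice 2, PD to slice 1
  expect_equal(palliascreen:::slice_of_offset(c(0L, 29L, 30L, 89L, 90L,
                                                179L, 180L, 364L, 365L, -1L)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, NA, NA))
})

test_that("slice counts place each event in exactly one slice", {
  inst <- instance_fixture(pd = 2000L, offsets_codes = tibble::tibble(
    offset = c(5, 10, 40, 400), category = "ICD9", code = "410.1"))
  counts <- slice_code_counts(inst)
  icd <- counts[counts$code == "410.1", ]
  expect_equal(icd$slice, c(1L, 2L))
  expect_equal(icd$count, c(2, 1))  # the offset-400 event is outside the window

  empty <- instance_fixture(pd = 2000L)
  sc <- slice_code_counts(empty)
  expect_false(any(sc$category != "ENCOUNTER"))  # only the history encounter
})

test_that("summary statistics follow the hand computations over active days", {
  # two active days with tallies {3, 1}
  inst <- instance_fixture(pd = 2000L, offsets_codes = tibble::tibble(
    offset = c(5, 5, 5, 50), category = "ICD9",
    code = c("a", "a", "b", "c")))
  st <- category_summary_stats(inst, "ICD9")
  got <- setNames(st$value, st$stat)
  expect_equal(got[["unique_count"]], 3)
  expect_equal(got[["total_count"]], 4)
  expect_equal(got[["max_per_day"]], 3)
  expect_equal(got[["min_nonzero_per_day"]], 1)
  expect_equal(got[["range_per_day"]], 2)
  expect_equal(got[["mean_per_day"]], 2)
  expect_equal(got[["var_per_day"]], 1)  # population variance of {3, 1}

  # single active day, 4 events of 2 distinct codes
  inst2 <- instance_fixture(pd = 2000L, offsets_codes = tibble::tibble(
    offset = rep(7, 4), category = "RXCUI", code = c("x", "x", "y", "y")))
  st2 <- category_summary_stats(inst2, "RXCUI")
  got2 <- setNames(st2$value, st2$stat)
  expect_equal(got2[["unique_count"]], 2)
  expect_equal(got2[["total_count"]], 4)
  expect_equal(got2[["max_per_day"]], 4)
  expect_equal(got2[["min_nonzero_per_day"]], 4)
  expect_equal(got2[["range_per_day"]], 0)
  expect_equal(got2[["var_per_day"]], 0)

  # category absent from the window emits nothing
  expect_equal(nrow(category_summary_stats(inst2, "CPT")), 0)
})

test_that("demographics yield age at PD and one-hot factors", {
  inst <- instance_fixture(pd = 2000L, birth = 2000L - 29600L, gender = "MALE")
  d <- demographic_features(inst)
  expect_equal(d[["DEMO|age"]], 81)
  expect_equal(d[["DEMO|gender|MALE"]], 1)
  expect_false("DEMO|gender|FEMALE" %in% names(d))

  born_on_pd <- instance_fixture(pd = 2000L, birth = 2000L)
  expect_equal(demographic_features(born_on_pd)[["DEMO|age"]], 0)
})

test_that("feature names serialize and parse losslessly", {
  names <- c("SLICE|ICD9|410.1|3", "STAT|ENCOUNTER|var_per_day",
             "DEMO|age", "DEMO|gender|MALE")
  p <- parse_feature_names(names)
  expect_equal(p$kind, c("SLICE", "STAT", "DEMO", "DEMO"))
  expect_equal(p$code[1], "410.1")
  expect_equal(p$slice[1], 3L)
  expect_equal(p$stat[2], "var_per_day")
  expect_equal(p$field[3:4], c("age", "gender"))
  # reconstruct
  rebuilt <- c(
    palliascreen:::serialize_feature("SLICE", p$category[1], p$code[1], p$slice[1]),
    palliascreen:::serialize_feature("STAT", p$category[2], p$stat[2]),
    "DEMO|age",
    palliascreen:::serialize_feature("DEMO", p$field[4], p$level[4])
  )
  expect_equal(rebuilt, names)
})

test_that("vocabulary pruning keeps features supported by > threshold patients", {
  # code "common" in 101 patients, code "rare" in 100, threshold 100
  n <- 120
  inst <- tibble::tibble(patient_id = sprintf("p%03d", 1:n),
                         prediction_date = 1000L, label = 0L,
                         admitted = FALSE, censor_length = NA_integer_)
  ev <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("p%03d", 1:101), date = 995L,
                   category = "ICD9", code = "common",
                   encounter_type = NA_character_),
    tibble::tibble(patient_id = sprintf("p%03d", 1:100), date = 990L,
                   category = "CPT", code = "rare",
                   encounter_type = NA_character_)
  )
  co <- structure(list(
    instances = inst, events = ev,
    patients = make_patients(inst$patient_id),
    exclusions = tibble::tibble(patient_id = character(), reason = character())
  ), class = "mortality_cohort")
  voc <- build_vocabulary(co, min_patient_support = 100L)
  expect_true("SLICE|ICD9|common|1" %in% voc$feature)
  expect_false("SLICE|CPT|rare|1" %in% voc$feature)
  expect_false(any(grepl("STAT\\|CPT", voc$feature)))  # CPT stats also at 100
  expect_true(all(grepl("^DEMO", voc$feature) |
                    voc$support > 100))  # DEMO kept regardless
  # monotone: a higher threshold never adds features
  voc_hi <- build_vocabulary(co, min_patient_support = 110L)
  expect_true(all(voc_hi$feature %in% voc$feature))
  # determinism
  expect_equal(build_vocabulary(co, 100L), voc)
  expect_error(build_vocabulary(cohort_subset(co, patient_ids = character(0))),
               "empty training set")
})

test_that("vectorization matches the vocabulary and permutes with its input", {
  pop <- random_population(41, n = 80)
  co <- build_cohort(pop)
  voc <- vocab_of(co)
  fm <- vectorize(co, voc)
  expect_equal(dim(fm$matrix), c(nrow(co$instances), nrow(voc)))
  expect_equal(fm$labels, co$instances$label)
  expect_true(all(fm$matrix@x > 0))  # explicit zeros never stored
  # permuted instance list -> same matrix with permuted rows
  perm <- sample(nrow(co$instances))
  co2 <- co
  co2$instances <- co$instances[perm, ]
  fm2 <- vectorize(co2, voc)
  expect_equal(fm2$matrix, fm$matrix[perm, ])
  # instance with nothing in vocabulary -> all-zero row
  lone <- instance_fixture(pd = 9000L)
  fm3 <- vectorize(lone, voc[voc$kind == "SLICE", ][1:3, ])
  expect_equal(Matrix::nnzero(fm3$matrix), 0)
})

test_that("slice counts conserve window totals and category totals", {
  pop <- random_population(53, n = 100)
  co <- build_cohort(pop)
  f <- palliascreen:::compute_features(co)
  parsed <- dplyr::inner_join(f, parse_feature_names(unique(f$feature)),
                              by = "feature")
  slice_sum <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(parsed, kind == "SLICE"),
                    patient_id, category, code),
    total = sum(value), .groups = "drop")
  # sum over slices equals the direct window count of each code
  ev <- dplyr::inner_join(co$events,
                          co$instances[, c("patient_id", "prediction_date")],
                          by = "patient_id")
  ev <- dplyr::filter(ev, prediction_date - date >= 0, prediction_date - date < 365)
  direct <- dplyr::count(ev, patient_id, category, code, name = "n")
  cmp <- dplyr::full_join(slice_sum, direct,
                          by = c("patient_id", "category", "code"))
  expect_true(all(cmp$total == cmp$n))
  # and equals the STAT total_count per category
  stat_total <- dplyr::filter(parsed, kind == "STAT", stat == "total_count")
  cat_sum <- dplyr::summarise(dplyr::group_by(slice_sum, patient_id, category),
                              total = sum(total), .groups = "drop")
  cmp2 <- dplyr::inner_join(stat_total, cat_sum, by = c("patient_id", "category"))
  expect_equal(nrow(cmp2), nrow(stat_total))
  expect_true(all(cmp2$value == cmp2$total))
  # non-negativity of derived statistics
  expect_true(all(dplyr::filter(parsed, stat %in%
    c("var_per_day", "range_per_day"))$value >= 0))
})

test_that("vocabulary and matrix serialize to text and back", {
  pop <- random_population(61, n = 50)
  co <- build_cohort(pop)
  voc <- vocab_of(co)
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(voc, vp)
  expect_equal(read_vocabulary(vp), voc, ignore_attr = TRUE)

  fm <- vectorize(co, voc)
  mp <- withr::local_tempfile(fileext = ".mtx")
  write_feature_matrix(fm, mp)
  back <- read_feature_matrix(mp)
  expect_equal(as.matrix(back$matrix), as.matrix(fm$matrix))
  expect_equal(back$labels, fm$labels)
  expect_equal(back$row_ids, fm$row_ids)
})
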