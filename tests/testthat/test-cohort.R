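# brute-force candidate rules used as the oracle for the worked examples
brute_positive <- function(enc, first_enc, death) {
  sort(Filter(function(d) d >= death - 365 && d <= death - 90 &&
                d >= first_enc + 365, enc))
}
brute_negative <- function(enc, first_enc, last_event) {
  sort(Filter(function(d) d >= first_enc + 365 && d <= last_event - 365, enc))
}

test_that("positive candidate dates satisfy all three constraints", {
  p <- one_patient(c(0, 400, 500, 600), death = 650L)
  expect_equal(candidate_dates_positive(p), brute_positive(c(0, 400, 500, 600), 0, 650))
  expect_equal(candidate_dates_positive(p), c(400L, 500L))

  # no date can be both >= 365 after first encounter and <= death - 90
  p2 <- one_patient(c(0, 100, 200), death = 300L)
  expect_equal(candidate_dates_positive(p2), integer(0))

  # boundary: 370 is within [death-365, death-90] and >= first + 365
  p3 <- one_patient(c(0, 370), death = 500L)
  expect_equal(candidate_dates_positive(p3), 370L)

  expect_error(candidate_dates_positive(one_patient(c(0, 400))), "death_date")
})

test_that("negative candidate dates satisfy both constraints, bounds inclusive", {
  expect_equal(candidate_dates_negative(one_patient(c(0, 400, 800))), 400L)
  expect_equal(candidate_dates_negative(one_patient(c(0, 300))), integer(0))
  expect_equal(candidate_dates_negative(one_patient(c(0, 365, 730))), 365L)
  expect_error(candidate_dates_negative(one_patient(c(0, 400), death = 600L)),
               "without a death_date")
})

test_that("selection takes earliest for positives, latest for negatives", {
  pos <- one_patient(c(0, 400, 500), death = 700L)
  expect_equal(select_prediction_date(pos),
               list(prediction_date = 400L, admitted = FALSE))

  neg <- one_patient(c(0, 365, 400, 800))
  expect_equal(select_prediction_date(neg),
               list(prediction_date = 400L, admitted = FALSE))

  expect_null(select_prediction_date(one_patient(c(0, 100), death = 900L)))
})

test_that("inpatient candidates are preferred and moved to the admission's second day", {
  # candidates 400 (outpatient) and 500 (inside admission days 499-510):
  # restrict to inpatient, then second day of admission = 500 -> 500 is day 2
  p <- one_patient(enc_dates = c(0, 400, 499:510), death = 700L,
                   enc_types = c("OUTPATIENT", "OUTPATIENT", rep("INPATIENT", 12)))
  sel <- select_prediction_date(p)
  expect_true(sel$admitted)
  expect_equal(sel$prediction_date, 500L)

  # second-day adjustment reverts (admitted stays TRUE) when it would break
  # the constraints: candidate 610 = death - 90 exactly, admission 610-615,
  # second day 611 > death - 90
  p2 <- one_patient(enc_dates = c(0, 400, 610:615), death = 700L,
                    enc_types = c("OUTPATIENT", "OUTPATIENT", rep("INPATIENT", 6)))
  sel2 <- select_prediction_date(p2)
  expect_true(sel2$admitted)
  expect_equal(sel2$prediction_date, 610L)

  # an admission starting before the candidate: second day counts from the
  # admission start, not the candidate
  p3 <- one_patient(enc_dates = c(0, 497:505), death = 800L,
                    enc_types = c("OUTPATIENT", rep("INPATIENT", 9)))
  sel3 <- select_prediction_date(p3)
  expect_true(sel3$admitted)
  expect_equal(sel3$prediction_date, 498L)  # earliest candidate 497 is span start
})

test_that("build_cohort censors at the prediction date and labels by 365-day death", {
  pop <- toy_population()
  co <- build_cohort(pop)
  expect_s3_class(co, "mortality_cohort")
  # alice: candidates in [535, 810] & >= 365 -> encounters 600, 700; earliest 600
  alice <- co$instances[co$instances$patient_id == "alice", ]
  expect_equal(alice$prediction_date, 600L)
  expect_equal(alice$label, 1L)
  expect_equal(alice$censor_length, 300L)
  expect_true(all(co$events$date[co$events$patient_id == "alice"] <= 600))
  # bob: negative, candidates {500, 600} (within [365, 1100-365]); latest -> 600
  bob <- co$instances[co$instances$patient_id == "bob", ]
  expect_equal(bob$prediction_date, 600L)
  expect_equal(bob$label, 0L)
  # carol infeasible -> excluded, conservation holds
  expect_equal(co$exclusions$patient_id, "carol")
  expect_equal(nrow(co$instances) + nrow(co$exclusions), 3)
})

test_that("patients with short histories are all excluded", {
  pop <- ehr_population(
    make_patients(c("a", "b"), death = c(NA, 300L)),
    dplyr::bind_rows(make_events("a", c(0, 100, 200)),
                     make_events("b", c(0, 50)))
  )
  co <- build_cohort(pop)
  expect_equal(nrow(co$instances), 0)
  expect_equal(nrow(co$exclusions), 2)
})

test_that("cohort interval invariants hold on random synthetic populations", {
  for (seed in c(3, 21, 77)) {
    pop <- random_population(seed, n = 120)
    co <- build_cohort(pop)
    inst <- dplyr::inner_join(co$instances,
                              palliascreen:::patient_timelines(pop),
                              by = "patient_id")
    pos <- dplyr::filter(inst, label == 1)
    neg <- dplyr::filter(inst, label == 0)
    expect_true(all(pos$death_date - pos$prediction_date >= 90))
    expect_true(all(pos$death_date - pos$prediction_date <= 365))
    expect_true(all(pos$prediction_date - pos$first_encounter >= 365))
    expect_true(all(neg$last_event - neg$prediction_date >= 365))
    # censoring: no event after its instance's prediction date
    joined <- dplyr::inner_join(co$events,
                                co$instances[, c("patient_id", "prediction_date")],
                                by = "patient_id")
    expect_true(all(joined$date <= joined$prediction_date))
    # idempotence / order-insensitivity
    shuffled <- ehr_population(pop$patients[sample(nrow(pop$patients)), ],
                               pop$events[sample(nrow(pop$events)), ])
    co2 <- build_cohort(shuffled)
    expect_equal(co2$instances, co$instances)
  }
})

test_that("split_cohort is a deterministic patient-level multinomial partition", {
  pop <- random_population(13, n = 400)
  co <- build_cohort(pop)
  n <- nrow(co$instances)
  s1 <- split_cohort(co, seed = 7)
  s2 <- split_cohort(co, seed = 7)
  expect_equal(s1$instances$split, s2$instances$split)
  expect_setequal(unique(s1$instances$split),
                  intersect(c("train", "validation", "test"),
                            unique(s1$instances$split)))
  # sizes within 3 multinomial standard errors of expectation
  for (grp in c("train", "validation", "test")) {
    p <- c(train = 0.8, validation = 0.1, test = 0.1)[[grp]]
    got <- sum(s1$instances$split == grp)
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  # degenerate ratios put everything in train
  all_train <- split_cohort(co, ratios = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$instances$split == "train"))
  # disjoint and exhaustive by construction of the column
  expect_equal(sort(unlist(lapply(c("train", "validation", "test"), function(g)
    cohort_subset(s1, g)$instances$patient_id))),
    sort(co$instances$patient_id))
})

test_that("censor-length curves separate the classes at 365 days", {
  pop <- random_population(29, n = 250)
  co <- build_cohort(pop)
  curve <- censor_length_curve(co)
  pos <- dplyr::filter(curve, label == 1)
  neg <- dplyr::filter(curve, label == 0)
  # positives all die within 365 days of PD: survival hits 0 by t = 365
  expect_lte(max(pos$t), 365)
  expect_equal(pos$fraction_exceeding[which.max(pos$t)], 0)
  # negatives all have > 364 days of follow-up
  expect_true(all(neg$fraction_exceeding[neg$t < 365] == 1))
  # single instance: step function dropping at its censor length
  single <- co
  single$instances <- co$instances[1, ]
  sc <- censor_length_curve(single)
  len <- co$instances$censor_length[1]
  expect_equal(sc$fraction_exceeding[sc$t == len], 0)
  expect_true(all(sc$fraction_exceeding[sc$t < len] == 1))
})
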