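---
title: "Screening for palliative-care needs from coded EHR histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for palliative-care needs from coded EHR histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Palliative-care teams cannot chart-review every hospital admission. A
pragmatic proxy is 12-month all-cause mortality: patients likely to die
within a year are, with high probability, patients who would benefit from a
goals-of-care conversation. `palliascreen` implements the full pipeline for
this screening problem on longitudinal coded EHR data — diagnoses (ICD-9),
procedures (CPT), medications (RXCUI) and encounters, each a dated opaque
token per patient.

Formally: given a patient and a *prediction date* (PD), predict the
probability that the patient dies within 365 days after PD, using only
events from the 365 days up to and including PD.

All dates in the package are integer day indices on an arbitrary epoch.
Calendar months never appear: "3 months" is fixed as 90 days and "12
months" as 365 days, which makes every temporal constraint exact integer
arithmetic and therefore exactly testable.

```{r, message = FALSE}
library(palliascreen)
```

## Cohort construction

Supervised labels for this problem are only valid under temporal
constraints, which the cohort builder enforces per patient:

* **Positive cases** (recorded death): the PD must be a recorded encounter
  date, at least 90 and at most 365 days before death (death closer than 90
  days leaves no time to act; farther than 365 days makes the label
  negative), and at least 365 days after the first encounter (enough
  history to featurize).
* **Negative cases** (no recorded death): the PD must be an encounter date
  at least 365 days after the first encounter and at least 365 days before
  the last recorded event, so that one full label-validating year of
  follow-up is observed.

All bounds are inclusive: the constraints are phrased as "at least / at
most", and we admit the boundary (a death exactly 90 or 365 days after PD,
an encounter exactly 365 days from either end of the record).

Among the feasible candidates, dates inside an inpatient admission are
lexicographically preferred (restrict to them whenever any exist) — those
patients can be reached on the ward. Then positives take the *earliest*
candidate (maximal lead time before death) and negatives the *latest*
(maximal history). If the chosen date lies inside an admission, the
instance is flagged *admitted* and the PD is moved to the admission's
second day, when admission-driven documentation has caught up. Two
judgement calls deserve note:

* The second-day adjustment is re-verified against the interval
  constraints only, not against "must be a recorded encounter date" — the
  adjustment deliberately steps off the candidate grid, and demanding an
  encounter on the second day would make the adjustment a no-op in sparse
  records. If the adjusted date violates an interval constraint we keep the
  original date (the admitted flag stays).
* "Second day of admission" is admission start + 1 day, with admissions
  reconstructed as maximal runs of consecutive inpatient encounter days.

Patients with no feasible date are excluded, not errors; `build_cohort()`
returns them in an exclusion table so that every input patient is
accounted for. Records are right-censored at the PD (events strictly after
it are dropped) and the censor length — time to death for positives, to the
last recorded event for negatives — is kept for the class-separation
diagnostic `censor_length_curve()`: positive curves must reach zero at
t = 365, negative curves must stay at one until t = 365.

`split_cohort()` assigns patients to train/validation/test by an
independent multinomial draw with probabilities 8:1:1 — the realized sizes
are approximate by design, matching how such splits are reported in
practice.

## Featurization

The 365-day observation window is partitioned into four half-open,
recency-weighted slices anchored at the PD:

| slice | interval          | duration |
|-------|-------------------|----------|
| 1     | (PD−30, PD]       | 30 d     |
| 2     | (PD−90, PD−30]    | 60 d     |
| 3     | (PD−180, PD−90]   | 90 d     |
| 4     | (PD−365, PD−180]  | 185 d    |

The half-open `(start, end]` convention keeps the PD's own events (they
survive censoring, which removes only events *after* the PD), makes the
slices an exact partition of the window, and reproduces the printed
durations 30/60/90/185. An event exactly 30 days before PD falls in slice
2, not slice 1.

Three feature families are emitted per instance:

* `SLICE|category|code|k` — occurrences of each code in slice *k*. For
  encounter events the code is the encounter type, and inpatient
  admissions contribute one event per admitted day, so the slice count of
  `INPATIENT` is "days admitted in that slice".
* `STAT|category|stat` — per-category window summaries: distinct codes,
  total events, and the max / min / range / mean / variance of the daily
  event tally. Daily statistics are computed over *active days only* (days
  with at least one event of the category): the "minimum (non-zero) per
  day" statistic forces this for the minimum, and we apply the same
  convention to mean and variance for coherence rather than mixing
  active-day and calendar-day denominators. The variance is the population
  variance (divide by the number of active days); with a single active day
  it is 0, and a category absent from the window emits no statistics at
  all.
* `DEMO|…` — age in completed years at the PD,
  `floor((PD − birth_date)/365.25)`, plus one-hot gender, race and
  ethnicity with the category levels frozen by the training vocabulary.

The vocabulary is built on the training split only — support pruning on
validation or test data would leak label-adjacent information — and drops
every SLICE/STAT feature with a patient support of 100 or fewer
(`min_patient_support`, configurable); demographics are always retained.
Features are ordered lexicographically by their serialized name, so
identical training sets yield byte-identical vocabularies. `vectorize()`
produces a sparse instance-by-feature matrix; explicit zeros are never
stored. No feature is scaled or standardized anywhere in the pipeline.

## Model and training protocol

The classifier is a fully connected feedforward network: `hidden_layers`
layers of `hidden_width` units with SeLU activations (λ ≈ 1.0507,
α ≈ 1.6733; LeCun-normal initialization, the combination under which such
networks self-normalize), a sigmoid output and log loss. Setting
`hidden_layers = 0` gives the logistic-regression baseline through the
identical training loop. The full-scale configuration (18 × 512) is
supported; the package's own experiments use 2 × 64 so that a complete run
fits in minutes on one CPU — depth is a configuration axis, not a code
path.

Optimization is Adam (default learning rate 0.001, β₁ = 0.9, β₂ = 0.999)
on shuffled mini-batches of 128. There is no explicit regularization;
instead, model selection is done by *snapshots*: every 250 mini-batch
iterations (and at the final iteration) the current weights are scored by
average precision on the validation split, and the best snapshot —
earliest on ties — is returned. Average precision is the right selection
metric here because the cohort is heavily imbalanced and the use case is
precision-oriented retrieval ("surface the patients most likely to die").
The stopping rule is simply `max_iterations`, exposed in
`model_config()`; snapshot selection makes the exact value uncritical as
long as training has passed its validation peak.

Training is deterministic given `config$seed` on a fixed machine
(seeded initialization and shuffling, single-threaded dense algebra);
bitwise cross-platform identity is not promised.

## Evaluation

All metrics live in `evaluate_predictions()` and have fixed tie
conventions:

* **Average precision** — mean of precision at each positive's rank; runs
  of equal scores are treated as a block and the reported value is the
  exact expectation over random orderings within each block.
* **AUROC** — the Mann–Whitney probability that a random positive outscores
  a random negative, ties counted ½.
* **Interpolated PR curve** — one point per distinct threshold;
  interpolated precision at recall r is the maximum precision at any
  recall ≥ r (the standard information-retrieval interpolation, which is
  what `recall_at_precision()` inverts). The scalar `ap` reported is the
  *raw* average precision, not the interpolated area.
* **Brier score** — mean squared error of the probability.
* **Reliability curve** — ten equal-width, right-closed bins on [0, 1];
  empty bins are kept and flagged rather than silently dropped.

## The synthetic-EHR generator

Real clinical warehouses are proprietary, so the package ships a generator
(`sim_config()` / `generate_population()`) whose defaults define the study
conditions used by every test:

* ten-year calendar (3650 days), adults aged 30–90 at calendar start;
* encounters as a homogeneous Poisson process at 8 per patient-year; 0.3%
  of encounters are inpatient admissions lasting 1 + Poisson(3) days, each
  admitted day emitting an `INPATIENT` encounter event;
* each encounter emits Poisson(4) background codes from vocabularies of
  150/100/100 ICD9/CPT/RXCUI tokens;
* five planted ICD9 *risk codes* with log-hazard effects 3.0–5.0, each
  carried independently by 3% of patients and emitted at half of a
  carrier's encounters;
* death times exponential with annual hazard
  `0.002 × exp(sum of carried effects)`, recorded only when they fall
  inside the calendar span — later deaths are unobserved, exactly like a
  warehouse snapshot.

The proportional-hazards mechanism was chosen because it yields
closed-form survival fractions (the one-year death fraction with no risk
codes is `1 − exp(−h)`, tested at n = 10,000) and a planted,
recoverable signal with known effect sizes. The default signal strength
was fixed once, before the classifier existed, by requiring that a
univariate screen on planted-code counts alone exceed AUROC 0.75 (it
reaches ≈ 0.86, against an information ceiling of ≈ 0.88 for the true
latent score); under these conditions cohorts come out at roughly 8%
positive prevalence. What the generator deliberately does **not** emulate:
ICD/CPT semantics and hierarchy, comorbidity correlation structure, coding
practice drift, age-dependent hazards, and utilization that intensifies
before death. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that planted signal of realistic strength is
recovered — not that any particular performance level transfers to real
EHR data.

## Explanations

For a single instance, the influence of a code is the drop in
log-probability (natural log; the base only rescales all influences
uniformly) when *all* occurrences of that code are removed from the record
and **every** feature — slice counts *and* summary statistics — is
recomputed from the ablated event list. Recomputing the statistics is what
lets summary-statistic features receive credit through the codes that
drive them. Only codes observed in the window are scored: absent codes
have exactly zero influence (their ablation is the identity), and scoring
them would cost model evaluations for no information. Demographics get two
dedicated counterfactuals: age set to zero, and gender swapped to the
opposite sex (patients recorded as a gender other than male/female are
left unperturbed; race and ethnicity are never perturbed). The ablated
probability is clipped to [1e−12, 1 − 1e−12] before the log so influences
stay finite.

`explain_prediction()` keeps only factors with positive influence, ranks
them within display category (Diagnostic / Procedural / Medication /
Encounter / Demographic), breaks ties lexicographically by code so reports
are byte-reproducible, and truncates to the top 5 per category. An
optional mode additionally ablates each summary-statistic feature directly
(setting it to zero); it is off by default since the per-code ablation
already credits statistics indirectly.

## Deployment-time screening

`run_screen()` is the label-free variant of cohort construction, kept as a
separate code path on purpose: on a given day it takes every patient
currently inside an inpatient admission with at least a year of history
and no recorded death, featurizes them with that day as the PD, and
returns patients ranked by predicted probability. No label constraints
apply — those exist only to make *training* data valid.

## Numerical and size choices

* Problem sizes in the test suite: the cohort-constraint sweep uses 200
  populations of 500 patients; conservation checks use ~10,000 instances;
  the signal-recovery study trains a 2 × 64 network on 10,000 patients for
  2,000 mini-batches (8 snapshots). These sizes make the full suite run in
  minutes while keeping every binomial bound meaningful.
* Metric oracles: AP and AUROC are verified to 1e−10 against exhaustive
  enumeration (per-block arrangements for AP, all positive–negative pairs
  for AUROC) on 1,000 random tied score sets.
* Degenerate inputs: empty populations, empty candidate sets, categories
  absent from a window, all-tied scores, empty reliability bins, and
  single-example inputs all have defined, tested behavior.

## Known limitations

* The generator's independence assumptions (codes independent given the
  carrier indicators, constant hazard) understate the difficulty of real
  EHR prediction; reported metrics on synthetic data are demonstrations,
  not benchmarks.
* Survival modeling (time-to-event) is intentionally out of scope: the
  problem is framed as binary 12-month mortality.
* No code-hierarchy rollups, lab values or vitals; features are counts of
  opaque tokens.
* Feature names use `|` as a separator, so code tokens may not contain it.
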