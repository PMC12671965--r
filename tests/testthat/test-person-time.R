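make_cohort_row <- function(patient_id, baseline, end, reason,
                            strategy = "tamoxifen") {
  tibble::tibble(
    patient_id = patient_id,
    baseline_date = as.Date(baseline),
    followup_end_date = as.Date(end),
    end_reason = reason,
    strategy = strategy
  )
}

test_that("expansion assigns deaths, truncates at 60 months and at admin end", {
  # death 10 days after baseline: a single record with the event
  co <- make_cohort_row("P1", "2010-01-01", "2010-01-11", "death")
  pp <- expand_person_periods(co)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$k, 0L)
  expect_equal(pp$Y_k, 1)

  # alive for the full 5 years: 60 event-free records
  co2 <- make_cohort_row(
    "P2", "2010-01-01", as.Date("2010-01-01") + floor(60 * 30.4375),
    "five_years"
  )
  pp2 <- expand_person_periods(co2)
  expect_equal(nrow(pp2), 60)
  expect_equal(unique(pp2$Y_k), 0)
  expect_equal(pp2$k, 0:59)

  # baseline 2015-10-01 against the 2015-12-31 administrative end:
  # 91 days of follow-up span 3 monthly intervals
  co3 <- make_cohort_row("P3", "2015-10-01", "2015-12-31", "admin_end")
  expect_equal(nrow(expand_person_periods(co3)), 3)

  # emigration drops the interval containing the emigration date
  # emigration on day 91 falls in the third interval (k = 2): dropped
  co4 <- make_cohort_row("P4", "2010-01-01", "2010-04-02", "emigration")
  expect_equal(nrow(expand_person_periods(co4)), 2)

  expect_error(
    expand_person_periods(
      make_cohort_row("P5", "2010-01-01", "2009-12-01", "death")
    ),
    "before baseline"
  )
})

test_that("person-time is conserved across the expansion", {
  reg <- simulate_registry(scenario_config(n_patients = 400, seed = 52))
  cohort <- build_cohort(reg)
  pp <- expand_person_periods(cohort)
  # per patient: records match the interval count implied by follow-up days
  fu <- as.numeric(cohort$followup_end_date - cohort$baseline_date)
  expected <- ifelse(
    cohort$end_reason == "death",
    pmin(floor(fu / 30.4375), 59) + 1,
    ifelse(cohort$end_reason == "emigration",
      pmin(floor(fu / 30.4375), 60),
      pmin(ceiling(fu / 30.4375), 60)
    )
  )
  got <- table(factor(pp$patient_id, levels = cohort$patient_id))
  expect_equal(as.integer(got), as.integer(expected))
  # at most one event per patient, always on the last record
  by_pat <- pp |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(
      n_ev = sum(Y_k),
      ev_last = all(Y_k[-dplyr::n()] == 0),
      consecutive = identical(k, 0:(dplyr::n() - 1L))
    )
  expect_true(all(by_pat$n_ev <= 1))
  expect_true(all(by_pat$ev_last))
  expect_true(all(by_pat$consecutive))
})

test_that("time-varying flags switch on at onset and respect drug windows", {
  co <- make_cohort_row(
    "P1", "2010-01-01", as.Date("2010-01-01") + floor(60 * 30.4375),
    "five_years"
  )
  pp <- expand_person_periods(co)
  base <- as.Date("2010-01-01")
  diagnoses <- tibble::tibble(
    patient_id = "P1", condition = "cerebrovascular_disease",
    date = base + ceiling(7 * 30.4375) # onset during month 7
  )
  drugs <- tibble::tibble(
    patient_id = "P1", drug_group = "opioids",
    date = base + ceiling(3 * 30.4375) # one fill in month 3
  )
  tv <- attach_time_varying(pp, co, diagnoses, drugs)
  # monotone diagnosis flag: off before the onset interval, on from k = 8
  expect_equal(unique(tv$tv_cerebrovascular_disease[tv$k <= 7]), 0)
  expect_equal(unique(tv$tv_cerebrovascular_disease[tv$k >= 8]), 1)
  # windowed drug flag: on while the fill lies within 183 days of the
  # interval start, off again afterwards
  on_months <- tv$k[tv$tv_opioids == 1]
  day_fill <- as.numeric(drugs$date - base)
  starts <- floor(tv$k * 30.4375)
  expect_equal(
    sort(on_months),
    sort(tv$k[starts >= day_fill & starts - 183 < day_fill])
  )
  expect_equal(max(on_months) - min(on_months), 5)

  # no records at all: flags equal baseline (all zero here)
  tv0 <- attach_time_varying(pp, co, empty_diagnoses(), empty_drug_covariates())
  expect_true(all(tv0$tv_diabetes == 0))
  expect_true(all(tv0$tv_opioids == 0))
})

test_that("per-protocol censoring keeps the deviation interval only as C_k", {
  co <- make_cohort_row(
    "P1", "2010-01-01", as.Date("2010-01-01") + floor(60 * 30.4375),
    "five_years"
  )
  pp <- expand_person_periods(co)
  dev <- tibble::tibble(patient_id = "P1", deviation_month = 22L)
  ppc <- censor_at_deviation(pp, dev)
  expect_equal(nrow(ppc), 23) # k = 0..22, the last flagged as censored
  expect_equal(sum(ppc$C_k), 1)
  expect_equal(ppc$k[ppc$C_k == 1], 22L)
  expect_equal(nrow(ppc[ppc$C_k == 0, ]), 22)

  # adherent patient: identical to the intention-to-treat records
  ppa <- censor_at_deviation(
    pp, tibble::tibble(patient_id = "P1", deviation_month = NA_integer_)
  )
  expect_equal(ppa$k, pp$k)
  expect_true(all(ppa$C_k == 0))

  # death in the deviation interval wins over censoring
  cod <- make_cohort_row("P2", "2010-01-01", "2010-08-01", "death")
  ppd <- expand_person_periods(cod)
  devd <- tibble::tibble(patient_id = "P2", deviation_month = max(ppd$k))
  ppdc <- censor_at_deviation(ppd, devd)
  expect_equal(sum(ppdc$Y_k), 1)
  expect_equal(sum(ppdc$C_k), 0)

  # deviation at interval 0 contradicts the episode invariant
  expect_error(
    censor_at_deviation(
      pp, tibble::tibble(patient_id = "P1", deviation_month = 0L)
    ),
    "impossible"
  )
})

test_that("the expanded table reproduces the Kaplan-Meier product limit", {
  skip_if_not_installed("survival")
  reg <- simulate_registry(scenario_config(n_patients = 60, seed = 77))
  cohort <- build_cohort(reg)
  pp <- expand_person_periods(cohort)
  # empirical discrete hazards from person-periods, per arm
  for (arm in unique(cohort$strategy)) {
    ppa <- pp[pp$strategy == arm, ]
    haz <- ppa |>
      dplyr::group_by(k) |>
      dplyr::summarise(h = mean(Y_k))
    surv_pp <- cumprod(1 - haz$h)
    d <- ppa |>
      dplyr::group_by(patient_id) |>
      dplyr::summarise(time = max(k) + 1, ev = max(Y_k))
    km <- survival::survfit(survival::Surv(time, ev) ~ 1, data = d)
    s <- summary(km, times = sort(unique(haz$k)) + 1, extend = TRUE)$surv
    expect_equal(surv_pp, s, tolerance = 1e-12)
  }
})
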