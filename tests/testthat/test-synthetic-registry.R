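test_that("generation is deterministic under seed and empty at n = 0", {
  cfg <- scenario_config(n_patients = 120, seed = 7)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$dispensations, r2$dispensations)
  expect_identical(r1$diagnoses, r2$diagnoses)
  expect_identical(r1$drug_covariates, r2$drug_covariates)

  r0 <- simulate_registry(scenario_config(n_patients = 0, seed = 7))
  expect_equal(nrow(r0$patients), 0)
  expect_equal(nrow(r0$dispensations), 0)
  expect_true(all(
    c("patient_id", "drug", "date", "pills", "strength") %in%
      names(r0$dispensations)
  ))
  expect_true(all(
    c("patient_id", "diagnosis_date", "surgery_date", "stage") %in%
      names(r0$patients)
  ))
})

test_that("generated dates respect diagnosis <= surgery <= first fill <= end", {
  reg <- simulate_registry(scenario_config(n_patients = 400, seed = 21))
  p <- reg$patients
  expect_true(all(p$diagnosis_date <= p$surgery_date))
  ff <- dplyr::summarise(
    dplyr::group_by(reg$dispensations, patient_id),
    first = min(date)
  )
  m <- dplyr::left_join(p, ff, by = "patient_id")
  expect_true(all(m$surgery_date <= m$first))
  end <- pmin(m$death_date, m$emigration_date, na.rm = TRUE)
  has_end <- !is.na(end)
  expect_true(all(m$first[has_end] <= end[has_end]))
  expect_true(all(p$age >= 40))
  expect_true(all(p$sex == "female"))
})

test_that("arm-specific chemotherapy use matches the calibrated registry mix", {
  # registry cohort shows ~30% chemotherapy among aromatase-inhibitor
  # initiators vs ~6% among tamoxifen initiators
  reg <- simulate_registry(scenario_config(n_patients = 20000, seed = 31))
  ff <- emutrial:::first_endocrine_fill(reg$dispensations)
  m <- dplyr::left_join(ff, reg$patients, by = "patient_id")
  chemo_ai <- mean(m$chemotherapy[m$strategy == "aromatase_inhibitor"])
  chemo_tam <- mean(m$chemotherapy[m$strategy == "tamoxifen"])
  expect_lt(abs(chemo_ai - 0.303), 0.03)
  expect_lt(abs(chemo_tam - 0.060), 0.03)
})

test_that("with no covariate effects the arm split follows the intercept", {
  p_target <- 0.64
  cfg <- scenario_config(
    n_patients = 20000, seed = 5,
    treatment_model_coefs = c("(Intercept)" = qlogis(p_target))
  )
  pop <- generate_population(cfg)
  ds <- generate_dispensations(pop, cfg)
  p_hat <- mean(ds$assignments$first_class == "aromatase_inhibitor")
  expect_lt(abs(p_hat - p_target), 0.02)
})

test_that("degenerate adherence settings behave as specified", {
  # discontinuation hazard 0, prompt refills: nobody ever has a 60-day gap
  cfg0 <- scenario_config(
    n_patients = 150, seed = 9,
    adherence_params = list(
      disc_hazard_ai = 0, disc_hazard_tam = 0, p_switch = 0,
      p_prompt_refill = 1, refill_delay_mean = 0
    ),
    emigration_rate = 0
  )
  pop <- generate_population(cfg0)
  ds <- generate_dispensations(pop, cfg0)
  gaps <- ds$dispensations |>
    dispensation_duration() |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(
      max_gap = if (dplyr::n() > 1) {
        max(as.numeric(diff(date)) - head(duration_days, -1))
      } else {
        0
      }
    )
  expect_true(all(gaps$max_gap < 60))
  expect_true(all(is.na(ds$assignments$stop_day)))

  # discontinuation hazard 1 at the first interval: exactly one fill each
  cfg1 <- scenario_config(
    n_patients = 80, seed = 9,
    adherence_params = list(
      disc_hazard_ai = 1, disc_hazard_tam = 1, p_switch = 0
    )
  )
  ds1 <- generate_dispensations(generate_population(cfg1), cfg1)
  expect_true(all(table(ds1$dispensations$patient_id) == 1))
})

test_that("interval hazards reproduce geometric survival and null effects", {
  # constant hazard 0.01/month, no covariates, no censoring:
  # 5-year risk must approach 1 - 0.99^60 = 0.4528
  cfg <- scenario_config(
    n_patients = 20000, seed = 13,
    treatment_model_coefs = c("(Intercept)" = 0),
    hazard_model_coefs = c("(Intercept)" = qlogis(0.01)),
    true_treatment_log_or = 0,
    emigration_rate = 0
  )
  pop <- generate_population(cfg)
  ds <- generate_dispensations(pop, cfg)
  out <- generate_outcomes(pop$patients, ds$assignments, cfg)
  # count deaths within 60 intervals of the enrollment date
  dd <- as.numeric(out$death_date - out$.enroll_date)
  risk <- mean(!is.na(dd) & dd < 60 * cfg$interval_days)
  expect_lt(abs(risk - (1 - 0.99^60)), 0.012)

  # hazard ~ 0: no deaths at all
  cfg0 <- scenario_config(
    n_patients = 500, seed = 13,
    hazard_model_coefs = c("(Intercept)" = -40)
  )
  pop0 <- generate_population(cfg0)
  ds0 <- generate_dispensations(pop0, cfg0)
  out0 <- generate_outcomes(pop0$patients, ds0$assignments, cfg0)
  expect_true(all(is.na(out0$death_date)))
})

test_that("counterfactual truth matches closed forms and scales with n_mc", {
  # covariate-free hazards: risks equal 1 - (1 - p)^60 exactly
  p_ai <- 0.004
  p_tam <- 0.003
  cfg <- scenario_config(
    n_patients = 100, seed = 2,
    hazard_model_coefs = c("(Intercept)" = qlogis(p_tam)),
    true_treatment_log_or = qlogis(p_ai) - qlogis(p_tam)
  )
  tr <- true_counterfactual_risks(cfg, n_mc = 500)
  expect_equal(tr$risk_ai_5y, 1 - (1 - p_ai)^60, tolerance = 1e-10)
  expect_equal(tr$risk_tam_5y, 1 - (1 - p_tam)^60, tolerance = 1e-10)
  expect_equal(tr$true_rd, tr$risk_ai_5y - tr$risk_tam_5y, tolerance = 1e-12)
  expect_equal(tr$true_rr, tr$risk_ai_5y / tr$risk_tam_5y, tolerance = 1e-12)

  # null treatment effect: risk ratio 1 up to Monte Carlo error
  tr_null <- true_counterfactual_risks(
    scenario_config(n_patients = 100, seed = 2, true_treatment_log_or = 0),
    n_mc = 2000
  )
  expect_equal(tr_null$true_rr, 1, tolerance = 1e-10)
  expect_equal(tr_null$true_rd, 0, tolerance = 1e-10)

  # Monte Carlo SE shrinks like 1/sqrt(n)
  cfg_var <- scenario_config(n_patients = 100, seed = 2)
  se1 <- true_counterfactual_risks(cfg_var, n_mc = 1000)$mc_se[["rd"]]
  se4 <- true_counterfactual_risks(cfg_var, n_mc = 4000)$mc_se[["rd"]]
  expect_lt(abs(se4 / se1 - 0.5), 0.15)

  expect_error(true_counterfactual_risks(cfg, n_mc = 0), "positive")
})
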