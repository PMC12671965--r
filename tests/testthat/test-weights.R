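test_that("treatment weights match closed forms on a single binary confounder", {
  # P(A = ai | L = 1) = 0.8, P(A = ai | L = 0) = 0.5, half the cohort L = 1
  n <- 400
  cohort <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:n),
    L = rep(c(1, 0), each = n / 2),
    strategy = c(
      rep(c("aromatase_inhibitor", "tamoxifen"), times = c(160, 40)),
      rep(c("aromatase_inhibitor", "tamoxifen"), times = c(100, 100))
    )
  )
  w_unstab <- fit_iptw(cohort, covariates = "L", stabilize = FALSE)
  treated_L1 <- cohort$strategy == "aromatase_inhibitor" & cohort$L == 1
  expect_equal(unique(w_unstab$w_treatment[treated_L1]), 1 / 0.8,
    tolerance = 1e-6
  )
  # stabilized: marginal P(A = ai) = 0.65 here
  w_stab <- fit_iptw(cohort, covariates = "L", stabilize = TRUE)
  expect_equal(unique(w_stab$w_treatment[treated_L1]), 0.65 / 0.8,
    tolerance = 1e-6
  )
  expect_equal(mean(w_stab$w_treatment), 1, tolerance = 0.01)
  # no covariates: every stabilized weight is exactly 1
  w_null <- fit_iptw(cohort, covariates = character(0), stabilize = TRUE)
  expect_equal(unique(round(w_null$w_treatment, 12)), 1)
})

test_that("stabilized weighted arm sizes track the crude arm sizes", {
  reg <- simulate_registry(scenario_recovery(n_patients = 10000, seed = 61))
  cohort <- build_cohort(reg)
  w <- fit_iptw(cohort)
  s <- tapply(w$w_treatment, cohort$strategy, sum)
  n_arm <- table(cohort$strategy)
  expect_lt(abs(s[["aromatase_inhibitor"]] / n_arm[["aromatase_inhibitor"]] - 1), 0.01)
  expect_lt(abs(s[["tamoxifen"]] / n_arm[["tamoxifen"]] - 1), 0.01)
  # truncation caps the extremes
  w_tr <- fit_iptw(cohort, truncate_pct = 0.05)
  expect_lte(max(w_tr$w_treatment), quantile(w$w_treatment, 0.95) + 1e-9)
  expect_true(any(w_tr$truncated))
})

test_that("weighting balances the modelled covariates", {
  reg <- simulate_registry(scenario_recovery(n_patients = 20000, seed = 62))
  cohort <- build_cohort(reg)
  w <- fit_iptw(cohort)
  bal <- covariate_balance(cohort, w)
  expect_gt(max(abs(bal$smd_unweighted)), 0.2) # confounding designed in
  expect_lt(max(abs(bal$smd_weighted)), 0.05)
})

test_that("censoring weights reduce to closed forms", {
  # nobody deviates: all weights exactly 1
  co <- tibble::tibble(
    patient_id = c("P1", "P2"),
    baseline_date = as.Date("2010-01-01"),
    followup_end_date = as.Date("2010-01-01") + floor(60 * 30.4375),
    end_reason = "five_years",
    strategy = c("aromatase_inhibitor", "tamoxifen")
  )
  pp <- expand_person_periods(co)
  pp$C_k <- 0
  wc <- fit_ipcw(pp, co, covariates = character(0))
  expect_true(all(wc$w_censor == 1))

  # constant censoring probability 0.05, no covariates:
  # W_k = (1/0.95)^k, so 1.166 at k = 3
  set.seed(8)
  n <- 4000
  co2 <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:n),
    baseline_date = as.Date("2010-01-01"),
    followup_end_date = as.Date("2010-01-01") + floor(60 * 30.4375),
    end_reason = "five_years",
    strategy = rep(c("aromatase_inhibitor", "tamoxifen"), n / 2)
  )
  pp2 <- expand_person_periods(co2, max_months = 8)
  dev_month <- vapply(seq_len(n), function(i) {
    g <- which(stats::rbinom(7, 1, 0.05) == 1)
    if (length(g)) g[1] else NA_integer_
  }, 1L)
  pp2c <- censor_at_deviation(
    pp2, tibble::tibble(patient_id = co2$patient_id, deviation_month = dev_month)
  )
  wc2 <- fit_ipcw(pp2c, co2, covariates = character(0), spline = spline_spec(c(2, 4, 6)))
  # intercept-plus-spline model over 8 intervals fits a near-constant 5%
  w_k3 <- wc2$w_censor[wc2$k == 3]
  expect_equal(mean(w_k3), (1 / 0.95)^3, tolerance = 0.02)
  # monotone within patient
  mono <- tapply(wc2$w_censor, wc2$patient_id, function(x) all(diff(x) >= -1e-12))
  expect_true(all(mono))
})

test_that("covariate-dependent censoring weights match a brute-force product", {
  # censoring depends only on a baseline flag: weights are constant within
  # flag stratum at each interval and equal the hand-computed product
  set.seed(99)
  n <- 3000
  flag <- rep(c(1, 0), n / 2)
  p_cens <- ifelse(flag == 1, 0.10, 0.03)
  co <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:n),
    baseline_date = as.Date("2010-01-01"),
    followup_end_date = as.Date("2010-01-01") + floor(60 * 30.4375),
    end_reason = "five_years",
    strategy = "aromatase_inhibitor",
    frail = flag
  )
  co$strategy[seq(1, n, 2)] <- "tamoxifen"
  pp <- expand_person_periods(co, max_months = 6)
  dev_month <- vapply(seq_len(n), function(i) {
    g <- which(stats::rbinom(5, 1, p_cens[i]) == 1)
    if (length(g)) g[1] else NA_integer_
  }, 1L)
  ppc <- censor_at_deviation(
    pp, tibble::tibble(patient_id = co$patient_id, deviation_month = dev_month)
  )
  wc <- fit_ipcw(ppc, co,
    covariates = "frail",
    spline = spline_spec(c(1.5, 3, 4.5))
  )
  # brute-force oracle: per (arm, stratum, k), empirical uncensored share
  dat <- dplyr::left_join(ppc, co[c("patient_id", "frail")], by = "patient_id")
  dat <- dplyr::left_join(dat, wc, by = c("patient_id", "k"))
  emp <- dat |>
    dplyr::filter(k >= 1) |>
    dplyr::group_by(strategy, frail, k) |>
    dplyr::summarise(p_unc = mean(C_k == 0), w = mean(w_censor), .groups = "drop") |>
    dplyr::arrange(strategy, frail, k) |>
    dplyr::group_by(strategy, frail) |>
    dplyr::mutate(w_oracle = cumprod(1 / p_unc))
  expect_equal(emp$w, emp$w_oracle, tolerance = 0.05)
  # weights constant within stratum at each k
  spread <- dat |>
    dplyr::group_by(strategy, frail, k) |>
    dplyr::summarise(s = diff(range(w_censor)), .groups = "drop")
  expect_lt(max(spread$s), 1e-8)
})

test_that("weight combination is an aligned elementwise product", {
  iptw <- tibble::tibble(
    patient_id = c("P1", "P2"), p_assigned = c(0.5, 0.5),
    w_treatment = c(2, 1.5), truncated = FALSE
  )
  # intention-to-treat: total equals the treatment weight
  w_itt <- combine_weights(iptw)
  expect_equal(w_itt$w_total, iptw$w_treatment)
  ipcw <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 2),
    k = c(0L, 1L, 0L, 1L),
    w_censor = c(1, 1.5, 1, 1)
  )
  w_pp <- combine_weights(iptw, ipcw)
  expect_equal(w_pp$w_total, c(2, 3, 1.5, 1.5))
  expect_error(
    combine_weights(iptw[1, ], ipcw),
    "without treatment weights"
  )
})
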