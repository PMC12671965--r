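small_registry <- function(n = 600, seed = 71, ...) {
  simulate_registry(scenario_config(n_patients = n, seed = seed, ...))
}

test_that("bootstrap is deterministic and degenerate at one replicate", {
  reg <- small_registry()
  cfg1 <- analysis_config(n_bootstrap = 1, seed = 5)
  b1 <- bootstrap_cis(reg, cfg1)
  expect_equal(nrow(b1$estimates), 1)
  expect_equal(b1$ci$lower, b1$ci$upper) # one replicate: degenerate CI
  expect_equal(
    unname(unlist(b1$estimates[1, c("rd", "rr")])),
    c(b1$ci$lower[b1$ci$measure == "rd"], b1$ci$lower[b1$ci$measure == "rr"])
  )

  cfg <- analysis_config(n_bootstrap = 25, seed = 9)
  b_a <- bootstrap_cis(reg, cfg)
  b_b <- bootstrap_cis(reg, cfg)
  expect_identical(b_a$estimates, b_b$estimates)
  expect_identical(b_a$ci, b_b$ci)
  expect_true(all(b_a$ci$lower <= b_a$ci$upper))
})

test_that("percentile machinery matches exhaustive enumeration on 3 points", {
  # all 27 equally likely resamples of three values: the percentile CI of
  # the resampled mean is known exactly
  vals <- c(1, 4, 10)
  grid <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  means <- apply(grid, 1, function(r) mean(vals[r]))
  oracle <- quantile(means, c(0.025, 0.975), names = FALSE, type = 1)
  withr::local_seed(2)
  draws <- replicate(40000, mean(sample(vals, 3, replace = TRUE)))
  got <- emutrial:::boot_percentile(draws, 0.95)
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("fast and general bootstrap engines agree on the ITT analysis", {
  reg <- small_registry(n = 500, seed = 73)
  cfg <- analysis_config(n_bootstrap = 40, seed = 11)
  fast <- bootstrap_cis(reg, cfg)
  # route the same replicates through the general engine
  prep <- emutrial:::prepare_analysis(reg, cfg, eligibility_criteria())
  st <- emutrial:::boot_state_general(prep, cfg, eligibility_criteria())
  n <- nrow(prep$cohort)
  est <- emutrial:::local_seed(cfg$seed, {
    t(vapply(
      seq_len(cfg$n_bootstrap),
      function(b) {
        smp <- sample.int(n, n, replace = TRUE)
        emutrial:::boot_replicate_general(st, smp)
      },
      numeric(5)
    ))
  })
  expect_equal(unname(as.matrix(fast$estimates)), unname(est), tolerance = 1e-6)
})

test_that("subgroups re-fit weights, partition the cohort, and need events", {
  reg <- small_registry(n = 1200, seed = 74)
  cfg <- analysis_config()
  full <- run_analysis(reg, cfg)
  young <- run_subgroup(reg, ~ age < 65, cfg)
  old <- run_subgroup(reg, ~ age >= 65, cfg)
  expect_equal(nrow(young$cohort) + nrow(old$cohort), nrow(full$cohort))
  # always-true predicate reproduces the main analysis exactly
  all_in <- run_subgroup(reg, ~ age > 0, cfg)
  expect_equal(all_in$effects$rd, full$effects$rd, tolerance = 1e-12)
  expect_equal(
    attr(all_in$weights, "model") %||% all_in$weights$w_treatment,
    full$weights$w_treatment %||% attr(full$weights, "model")
  )
  # a subgroup weight model is fitted within the subgroup, not reused
  w_young <- fit_iptw(young$cohort)
  expect_equal(young$weights$w_treatment[
    match(w_young$patient_id, young$weights$patient_id)
  ], w_young$w_treatment, tolerance = 1e-9)
  expect_error(
    run_subgroup(reg, ~ age > 200, cfg),
    "no patients left"
  )
})

test_that("sensitivity variants behave as designed", {
  # no missingness: complete-case equals the main analysis exactly
  reg0 <- simulate_registry(scenario_config(
    n_patients = 800, seed = 75,
    missing_rates = c(grade = 0, her2 = 0, education = 0, employment = 0)
  ))
  cfg <- analysis_config()
  main <- run_analysis(reg0, cfg)
  cc <- run_sensitivity(reg0, "complete_case", cfg)
  expect_equal(cc$effects$rd, main$effects$rd, tolerance = 1e-12)
  expect_equal(nrow(cc$cohort), nrow(main$cohort))

  # with missingness the complete-case cohort is strictly smaller
  reg1 <- small_registry(n = 800, seed = 76)
  cc1 <- run_sensitivity(reg1, "complete_case", cfg)
  expect_lt(nrow(cc1$cohort), nrow(run_analysis(reg1, cfg)$cohort))

  # no confounding: weighted and covariate-adjusted estimates agree
  reg_null <- simulate_registry(scenario_null(n_patients = 4000, seed = 77))
  iptw <- run_analysis(reg_null, analysis_config(adjustment = "iptw"))
  gform <- run_sensitivity(reg_null, "covariate_adjustment", cfg)
  expect_equal(iptw$effects$rd, gform$effects$rd, tolerance = 1.0)
  expect_lt(abs(iptw$effects$rd - gform$effects$rd), 1.0)
})

test_that("rendered tables follow the display precision conventions", {
  curve_at <- function(r60) {
    tibble::tibble(
      strategy = "x", month = 1:60, hazard = NA_real_,
      risk = seq(0, r60, length.out = 60)
    )
  }
  # risks 16.6% and 10.5%: the risk-difference cell reads 6.1
  ef <- effect_measures(curve_at(0.166), curve_at(0.105))
  tab <- render_effects_table(list("opioid users" = ef))
  expect_equal(tab$rd, "6.1")
  expect_equal(tab$risk_ai, "16.6")
  # a ratio of 1.5809... renders as 1.58
  expect_equal(tab$rr, fmt <- formatC(0.166 / 0.105, format = "f", digits = 2))
  expect_equal(tab$rr, "1.58")
  # empty input: headers only
  empty <- render_effects_table(list())
  expect_equal(nrow(empty), 0)
  expect_named(
    empty, c("analysis", "risk_ai", "risk_tam", "rd", "rr", "hr")
  )
  # percentage cells to one decimal
  expect_equal(render_pct_cell(2437, 8030), "2437 (30.3)")
  expect_equal(render_pct_cell(272, 4506), "272 (6.0)")
})

test_that("identical configuration and seed give byte-identical report files", {
  reg <- small_registry(n = 400, seed = 79)
  cfg <- analysis_config(n_bootstrap = 8, seed = 21)
  render_twice <- function(dir) {
    res <- list(
      itt = bootstrap_cis(reg, cfg),
      pp = run_analysis(reg, analysis_config(contrast = "per_protocol"))
    )
    render_tables(res, dir)
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_twice(d1)
  p2 <- render_twice(d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
})

test_that("registry IO round-trips and drives identical analyses", {
  reg <- small_registry(n = 300, seed = 80)
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  back <- read_registry(dir)
  a1 <- run_analysis(reg, analysis_config())
  a2 <- run_analysis(back, analysis_config())
  expect_equal(a1$effects$rd, a2$effects$rd, tolerance = 1e-12)
  expect_false(any(startsWith(names(back$patients), ".")))
})

test_that("tidiers and plots expose the results", {
  reg <- small_registry(n = 400, seed = 81)
  fit <- run_analysis(reg, analysis_config())
  td <- tidy(fit)
  expect_named(td, c("measure", "estimate"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$n_patients, nrow(fit$cohort))
  b <- bootstrap_cis(reg, analysis_config(n_bootstrap = 5, seed = 3))
  tb <- tidy(b)
  expect_named(tb, c("measure", "estimate", "conf.low", "conf.high"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(plot_balance(covariate_balance(fit$cohort, fit$weights)), "ggplot")
  expect_named(tidy(fit$fit_interaction), c("term", "estimate"))
})
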