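# Orchestration: full analysis runs, nonparametric bootstrap confidence
# intervals (resampling patients, re-fitting all weight and outcome models
# per replicate), subgroup restriction, and sensitivity variants.

#' Analysis configuration
#'
#' @param contrast `"itt"` (effect of the first dispensation, regardless of
#'   later adherence) or `"per_protocol"` (censor at the first deviation,
#'   with inverse-probability-of-censoring weights).
#' @param adjustment `"iptw"` (IP treatment weighting, the primary
#'   approach), `"covariate_in_model"` (baseline covariates in the outcome
#'   model, g-formula standardization) or `"none"`.
#' @param subgroup Optional one-sided formula on baseline covariates, e.g.
#'   `~ age >= 65`; the cohort is restricted and all models re-fitted
#'   within the subgroup.
#' @param missing_handling `"category"` (explicit missing level, default)
#'   or `"complete_case"` (drop patients with any missing category).
#' @param covariates Baseline covariates for the weight/adjustment models.
#' @param n_bootstrap Bootstrap replicates for confidence intervals.
#' @param seed Seed driving all resampling.
#' @param spline Follow-up time spline, see [spline_spec()].
#' @param grace_days Treatment-gap grace period (days) for the
#'   per-protocol deviation definition.
#' @param stabilize,truncate_pct Passed to [fit_iptw()].
#' @param level Confidence level for percentile intervals.
#' @return A list of class `emul_analysis_config`.
#' @export
analysis_config <- function(contrast = c("itt", "per_protocol"),
                            adjustment = c("iptw", "covariate_in_model", "none"),
                            subgroup = NULL,
                            missing_handling = c("category", "complete_case"),
                            covariates = baseline_covariate_names(),
                            n_bootstrap = 1000L,
                            seed = 1L,
                            spline = spline_spec(),
                            grace_days = 60,
                            stabilize = TRUE,
                            truncate_pct = NULL,
                            level = 0.95) {
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1", call. = FALSE)
  structure(
    list(
      contrast = match.arg(contrast),
      adjustment = match.arg(adjustment),
      subgroup = subgroup,
      missing_handling = match.arg(missing_handling),
      covariates = covariates,
      n_bootstrap = as.integer(n_bootstrap),
      seed = as.integer(seed),
      spline = spline,
      grace_days = grace_days,
      stabilize = stabilize,
      truncate_pct = truncate_pct,
      level = level
    ),
    class = "emul_analysis_config"
  )
}

apply_subgroup <- function(cohort, subgroup) {
  if (is.null(subgroup)) {
    return(cohort)
  }
  expr <- if (inherits(subgroup, "formula")) {
    rlang::f_rhs(subgroup)
  } else if (is.character(subgroup)) {
    rlang::parse_expr(subgroup)
  } else {
    stop("subgroup must be a one-sided formula or a string", call. = FALSE)
  }
  keep <- rlang::eval_tidy(expr, data = cohort)
  if (!is.logical(keep) || length(keep) != nrow(cohort)) {
    stop("subgroup predicate must evaluate to one logical per patient",
      call. = FALSE
    )
  }
  cohort[keep & !is.na(keep), , drop = FALSE]
}

drop_missing_category <- function(cohort) {
  fac <- names(cohort)[vapply(cohort, is.factor, TRUE)]
  any_missing <- Reduce(`|`, lapply(fac, function(nm) {
    cohort[[nm]] == "missing"
  }), accumulate = FALSE)
  out <- cohort[!any_missing, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("complete-case cohort is empty", call. = FALSE)
  }
  droplevels(out)
}

# Shared preparation: cohort (after missing-handling and subgroup
# restriction), person-period tables and deviation months.
prepare_analysis <- function(registry, config, criteria) {
  cohort <- build_cohort(registry, criteria)
  ledger <- exclusion_ledger(cohort)
  if (config$missing_handling == "complete_case") {
    cohort <- drop_missing_category(cohort)
  }
  cohort <- apply_subgroup(cohort, config$subgroup)
  if (nrow(cohort) == 0) stop("no patients left after restriction", call. = FALSE)

  pp_itt <- expand_person_periods(
    cohort, criteria$interval_days, criteria$max_months
  )
  pp_model <- pp_itt
  if (config$contrast == "per_protocol") {
    disp <- registry$dispensations[
      registry$dispensations$patient_id %in% cohort$patient_id, ,
      drop = FALSE
    ]
    episodes <- build_episodes(disp, cohort, config$grace_days)
    devm <- deviation_time(episodes, cohort, criteria$interval_days)
    pp_tv <- attach_time_varying(
      pp_itt, cohort, registry$diagnoses, registry$drug_covariates,
      interval_days = criteria$interval_days
    )
    pp_model <- censor_at_deviation(pp_tv, devm)
  }
  list(cohort = cohort, ledger = ledger, pp_itt = pp_itt, pp_model = pp_model)
}

fit_and_measure <- function(prep, config, criteria) {
  cohort <- prep$cohort
  pp <- prep$pp_model
  weights <- NULL
  iptw <- NULL
  covs <- NULL
  if (config$adjustment == "iptw") {
    iptw <- fit_iptw(cohort, config$covariates,
      stabilize = config$stabilize, truncate_pct = config$truncate_pct
    )
    ipcw <- NULL
    if (config$contrast == "per_protocol") {
      ipcw <- fit_ipcw(pp, cohort, config$covariates,
        spline = config$spline
      )
    }
    weights <- combine_weights(iptw, ipcw)
  } else if (config$adjustment == "covariate_in_model") {
    covs <- config$covariates
  }
  fit_i <- fit_pooled_logistic(pp, weights,
    include_interaction = TRUE,
    covariates = covs, cohort = cohort, spline = config$spline
  )
  fit_h <- fit_pooled_logistic(pp, weights,
    include_interaction = FALSE,
    covariates = covs, cohort = cohort, spline = config$spline
  )
  curve_ai <- standardized_risk_curve(
    fit_i, "aromatase_inhibitor", criteria$max_months
  )
  curve_tam <- standardized_risk_curve(fit_i, "tamoxifen", criteria$max_months)
  effects <- effect_measures(curve_ai, curve_tam, fit_h, criteria$max_months)
  list(
    weights = weights, iptw = iptw, fit_interaction = fit_i,
    fit_no_interaction = fit_h,
    curves = dplyr::bind_rows(curve_ai, curve_tam),
    effects = effects
  )
}

#' Run one full analysis
#'
#' Builds the cohort from the registry tables, applies the configured
#' contrast, adjustment, missing-data handling and subgroup restriction,
#' fits the weight and outcome models, and returns standardized risk
#' curves and 5-year effect measures (point estimates; see
#' [bootstrap_cis()] for intervals).
#'
#' @param registry Registry tables (list with `patients`, `dispensations`,
#'   `diagnoses`, `drug_covariates`).
#' @param config An [analysis_config()].
#' @param criteria An [eligibility_criteria()].
#' @return An object of class `emul_analysis` with elements `cohort`,
#'   `ledger`, `weights`, `fit_interaction`, `fit_no_interaction`,
#'   `curves`, `effects`, `config`.
#' @export
#' @examples
#' reg <- simulate_registry(scenario_config(n_patients = 800, seed = 3))
#' fit <- run_analysis(reg, analysis_config(contrast = "itt"))
#' fit$effects
run_analysis <- function(registry, config = analysis_config(),
                         criteria = eligibility_criteria()) {
  prep <- prepare_analysis(registry, config, criteria)
  res <- fit_and_measure(prep, config, criteria)
  structure(
    c(
      list(
        cohort = prep$cohort, ledger = prep$ledger,
        person_periods = prep$pp_model, config = config, criteria = criteria
      ),
      res
    ),
    class = "emul_analysis"
  )
}

#' @export
print.emul_analysis <- function(x, ...) {
  cat("<emul_analysis> ", x$config$contrast, "/", x$config$adjustment,
    ", n = ", nrow(x$cohort), "\n",
    sep = ""
  )
  print(x$effects)
  invisible(x)
}

boot_percentile <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

measure_names <- function() c("risk_ai_5y", "risk_tam_5y", "rd", "rr", "avg_hr")

effects_vector <- function(effects) {
  c(
    risk_ai_5y = effects$risk_ai_5y, risk_tam_5y = effects$risk_tam_5y,
    rd = effects$rd, rr = effects$rr, avg_hr = effects$avg_hr
  )
}

# Fast replicate engine for the weighted ITT analysis: the outcome model
# depends on person-periods only through (strategy, interval) cells, so
# each replicate collapses to 2 x K weighted event/at-risk totals.
boot_state_itt_iptw <- function(prep, config, criteria) {
  cohort <- prep$cohort
  K <- criteria$max_months
  pp <- prep$pp_itt
  n_int <- table(factor(pp$patient_id, levels = cohort$patient_id))
  n_int <- as.integer(n_int)
  died <- cohort$end_reason == "death"
  a <- as.numeric(cohort$strategy == "aromatase_inhibitor")
  S <- rcs_basis(0:(K - 1), config$spline)
  cell_design <- function(interaction) {
    Xs <- lapply(c(0, 1), function(av) {
      X <- cbind("(Intercept)" = 1, ai = av, S)
      if (interaction) {
        XI <- S * av
        colnames(XI) <- paste0("ai:", colnames(S))
        X <- cbind(X, XI)
      }
      X
    })
    rbind(Xs[[1]], Xs[[2]]) # rows: a=0 k=0..K-1, then a=1 k=0..K-1
  }
  list(
    n = nrow(cohort), a = a, n_int = n_int, died = died, K = K,
    X_A = cohort_design(cohort, config$covariates),
    X_cells_i = cell_design(TRUE),
    X_cells_h = cell_design(FALSE),
    stabilize = config$stabilize
  )
}

boot_replicate_itt_iptw <- function(st, counts) {
  fitA <- fit_logistic(st$X_A, st$a, w = counts)
  p1 <- rep(NA_real_, st$n)
  p1[fitA$keep] <- fitA$fitted
  p_assigned <- ifelse(st$a == 1, p1, 1 - p1)
  pa_marg <- sum(counts * st$a) / sum(counts)
  num <- if (st$stabilize) ifelse(st$a == 1, pa_marg, 1 - pa_marg) else 1
  cw <- counts * num / p_assigned
  cw[counts == 0] <- 0

  K <- st$K
  lev <- seq_len(K)
  cell_wy <- function(arm) {
    i <- st$a == arm
    fK <- factor(st$n_int[i], levels = lev)
    tot <- vapply(split(cw[i], fK), sum, numeric(1))
    at_risk <- rev(cumsum(rev(tot))) # patients with n_int > k
    ev <- vapply(split(cw[i] * st$died[i], fK), sum, numeric(1))
    list(w = unname(at_risk), y = unname(ev))
  }
  c0 <- cell_wy(0)
  c1 <- cell_wy(1)
  w <- c(c0$w, c1$w)
  y_prop <- ifelse(w > 0, c(c0$y, c1$y) / w, 0)
  use <- w > 0

  fit_i <- fit_logistic(st$X_cells_i[use, , drop = FALSE], y_prop[use], w[use])
  fit_h <- fit_logistic(st$X_cells_h[use, , drop = FALSE], y_prop[use], w[use])
  h_cells <- predict_logistic(fit_i$coefficients, st$X_cells_i)
  r0 <- 1 - prod(1 - h_cells[seq_len(K)])
  r1 <- 1 - prod(1 - h_cells[K + seq_len(K)])
  c(
    risk_ai_5y = r1, risk_tam_5y = r0, rd = 100 * (r1 - r0),
    rr = if (r0 > 0) r1 / r0 else NA_real_,
    avg_hr = exp(unname(fit_h$coefficients["ai"]))
  )
}

# General replicate engine: reuses the prepared person-period rows of the
# sampled patients and re-fits every model (treatment weights, censoring
# weights, outcome) on the resampled data.
boot_state_general <- function(prep, config, criteria) {
  cohort <- prep$cohort
  pp <- prep$pp_model
  ord <- order(match(pp$patient_id, cohort$patient_id), pp$k)
  pp <- pp[ord, , drop = FALSE]
  pidx <- match(pp$patient_id, cohort$patient_id)
  rows_by_patient <- split(seq_len(nrow(pp)), factor(pidx, levels = seq_len(nrow(cohort))))

  a_pat <- as.numeric(cohort$strategy == "aromatase_inhibitor")
  S <- rcs_basis(pp$k, config$spline)
  a_row <- a_pat[pidx]
  Xo <- cbind("(Intercept)" = 1, ai = a_row, S)
  XI <- S * a_row
  colnames(XI) <- paste0("ai:", colnames(S))
  Xo_i <- cbind(Xo, XI)

  Xcov_pat <- NULL
  if (config$adjustment == "covariate_in_model") {
    Xcov_pat <- cohort_design(cohort, config$covariates)
    Xcov_pat <- Xcov_pat[, colnames(Xcov_pat) != "(Intercept)", drop = FALSE]
    Xo <- cbind(Xo, Xcov_pat[pidx, , drop = FALSE])
    Xo_i <- cbind(Xo_i, Xcov_pat[pidx, , drop = FALSE])
  }

  X_ipcw <- NULL
  if (config$adjustment == "iptw" && config$contrast == "per_protocol") {
    tv_cols <- intersect(
      paste0("tv_", time_varying_covariate_names()), names(pp)
    )
    Xb <- cohort_design(cohort, config$covariates)
    X_ipcw <- cbind(
      Xb[pidx, , drop = FALSE], as.matrix(pp[tv_cols]),
      rcs_basis(pp$k, config$spline)
    )
  }

  list(
    n = nrow(cohort), cohort = cohort, pp = pp, pidx = pidx,
    rows_by_patient = rows_by_patient, a_pat = a_pat,
    X_A = if (config$adjustment == "iptw") {
      cohort_design(cohort, config$covariates)
    },
    Xo = Xo, Xo_i = Xo_i, Xcov_pat = Xcov_pat, X_ipcw = X_ipcw,
    y = pp$Y_k, Ck = pp[["C_k"]] %||% rep(0, nrow(pp)), k = pp$k,
    K = criteria$max_months, config = config
  )
}

boot_replicate_general <- function(st, smp) {
  cfg <- st$config
  rows_l <- st$rows_by_patient[smp]
  rows <- unlist(rows_l, use.names = FALSE)
  inst <- rep(seq_along(smp), lengths(rows_l)) # resampled-instance id
  a_inst <- st$a_pat[smp]

  w_row <- rep(1, length(rows))
  if (cfg$adjustment == "iptw") {
    counts <- tabulate(smp, st$n)
    fitA <- fit_logistic(st$X_A, st$a_pat, w = counts)
    p1 <- rep(NA_real_, st$n)
    p1[fitA$keep] <- fitA$fitted
    p_assigned <- ifelse(st$a_pat == 1, p1, 1 - p1)
    pa_marg <- sum(counts * st$a_pat) / sum(counts)
    num <- if (cfg$stabilize) ifelse(st$a_pat == 1, pa_marg, 1 - pa_marg) else 1
    w_t <- num / p_assigned
    w_row <- w_t[smp][inst]

    if (!is.null(st$X_ipcw)) {
      y_unc <- 1 - st$Ck[rows]
      at_risk <- st$k[rows] >= 1
      p_unc <- rep(1, length(rows))
      for (av in c(0, 1)) {
        sel <- which(a_inst[inst] == av & at_risk)
        if (!length(sel) || all(y_unc[sel] == 1)) next
        Xa <- st$X_ipcw[rows[sel], , drop = FALSE]
        keepc <- colnames(Xa) == "(Intercept)" |
          apply(Xa, 2, function(v) var(v) > 0)
        fitc <- fit_logistic(Xa[, keepc, drop = FALSE], y_unc[sel])
        p_unc[sel] <- fitc$fitted
      }
      # groupwise cumulative product within each resampled instance
      logw <- cumsum(log(1 / p_unc))
      first <- which(c(TRUE, inst[-1] != inst[-length(inst)]))
      start <- rep(logw[first] - log(1 / p_unc)[first], times = diff(c(first, length(inst) + 1)))
      w_row <- w_row * exp(logw - start)
    }
  }

  keep <- st$Ck[rows] == 0
  fit_i <- fit_logistic(st$Xo_i[rows[keep], , drop = FALSE], st$y[rows[keep]], w_row[keep])
  fit_h <- fit_logistic(st$Xo[rows[keep], , drop = FALSE], st$y[rows[keep]], w_row[keep])

  K <- st$K
  S <- rcs_basis(0:(K - 1), cfg$spline)
  risk_for <- function(av) {
    X <- cbind("(Intercept)" = 1, ai = av, S)
    XI <- S * av
    colnames(XI) <- paste0("ai:", colnames(S))
    X <- cbind(X, XI)
    b <- fit_i$coefficients
    if (is.null(st$Xcov_pat)) {
      h <- predict_logistic(b[colnames(X)], X)
      1 - prod(1 - h)
    } else {
      eta_t <- drop(X %*% b[colnames(X)])
      eta_c <- drop(st$Xcov_pat[smp, , drop = FALSE] %*% b[colnames(st$Xcov_pat)])
      H <- outer(eta_c, eta_t, function(cc, tt) plogis(cc + tt))
      surv <- apply(1 - H, 1, cumprod)
      1 - mean(surv[K, ])
    }
  }
  r1 <- risk_for(1)
  r0 <- risk_for(0)
  c(
    risk_ai_5y = r1, risk_tam_5y = r0, rd = 100 * (r1 - r0),
    rr = if (r0 > 0) r1 / r0 else NA_real_,
    avg_hr = exp(unname(fit_h$coefficients["ai"]))
  )
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples patients (not person-periods) with replacement, re-runs the
#' weight estimation and outcome models on every replicate, and returns
#' percentile confidence intervals for the 5-year risks, risk difference,
#' risk ratio and average hazard ratio. Deterministic under
#' `config$seed`. Replicates whose fits fail are dropped and counted; more
#' than 10% failures aborts.
#'
#' @param registry Registry tables.
#' @param config An [analysis_config()]; `n_bootstrap` and `seed` control
#'   the resampling.
#' @param criteria An [eligibility_criteria()].
#' @return An object of class `emul_boot`: `point` (the full-data
#'   [run_analysis()] result), `estimates` (one row per replicate), `ci`,
#'   `n_failed`.
#' @export
bootstrap_cis <- function(registry, config = analysis_config(),
                          criteria = eligibility_criteria()) {
  prep <- prepare_analysis(registry, config, criteria)
  point_fit <- fit_and_measure(prep, config, criteria)
  point <- structure(
    c(
      list(
        cohort = prep$cohort, ledger = prep$ledger,
        person_periods = prep$pp_model, config = config, criteria = criteria
      ),
      point_fit
    ),
    class = "emul_analysis"
  )

  fast <- config$contrast == "itt" && config$adjustment == "iptw"
  st <- if (fast) {
    boot_state_itt_iptw(prep, config, criteria)
  } else {
    boot_state_general(prep, config, criteria)
  }
  n <- nrow(prep$cohort)
  B <- config$n_bootstrap
  est <- matrix(NA_real_, B, 5, dimnames = list(NULL, measure_names()))
  local_seed(config$seed, {
    for (b in seq_len(B)) {
      smp <- sample.int(n, n, replace = TRUE)
      rep_est <- tryCatch(
        if (fast) {
          boot_replicate_itt_iptw(st, tabulate(smp, n))
        } else {
          boot_replicate_general(st, smp)
        },
        error = function(e) rep(NA_real_, 5)
      )
      est[b, ] <- rep_est
    }
  })
  ok <- stats::complete.cases(est[, c("risk_ai_5y", "risk_tam_5y", "rd"), drop = FALSE])
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * B) {
    stop(
      n_failed, " of ", B, " bootstrap replicates failed (> 10%); ",
      "check model specification or data size",
      call. = FALSE
    )
  }
  ci <- purrr::map_dfr(measure_names(), function(m) {
    q <- boot_percentile(est[ok, m], config$level)
    tibble::tibble(measure = m, lower = q[1], upper = q[2])
  })
  structure(
    list(
      point = point,
      estimates = tibble::as_tibble(est[ok, , drop = FALSE]),
      ci = ci,
      n_bootstrap = B,
      n_failed = n_failed,
      level = config$level
    ),
    class = "emul_boot"
  )
}

#' @export
print.emul_boot <- function(x, ...) {
  cat("<emul_boot> ", x$n_bootstrap, " replicates (",
    x$n_failed, " failed), ", round(100 * x$level), "% percentile CIs\n",
    sep = ""
  )
  pt <- effects_vector(x$point$effects)
  df <- dplyr::left_join(
    tibble::tibble(measure = measure_names(), estimate = unname(pt[measure_names()])),
    x$ci,
    by = "measure"
  )
  print(as.data.frame(df), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Subgroup analysis
#'
#' Restricts the cohort with a baseline-covariate predicate and re-runs the
#' whole analysis, re-fitting the weight models within the subgroup (the
#' full-cohort weights are never reused).
#'
#' @param registry Registry tables.
#' @param subgroup One-sided formula on baseline covariates, e.g.
#'   `~ chemotherapy == 1` or `~ opioids == 1 | antidepressants == 1`.
#' @param config,criteria As in [run_analysis()].
#' @return An `emul_analysis`.
#' @export
run_subgroup <- function(registry, subgroup, config = analysis_config(),
                         criteria = eligibility_criteria()) {
  config$subgroup <- subgroup
  out <- run_analysis(registry, config, criteria)
  arms_events <- out$person_periods |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(events = sum(.data$Y_k), .groups = "drop")
  if (any(arms_events$events == 0) || nrow(arms_events) < 2) {
    stop(
      "subgroup has an arm without events: ",
      paste(sprintf(
        "%s=%d", arms_events$strategy, arms_events$events
      ), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Sensitivity analyses
#'
#' Variant `"covariate_adjustment"` replaces IP weighting by baseline
#' covariates in the pooled logistic model with g-formula standardization;
#' `"complete_case"` drops patients with any missing category before the
#' main analysis.
#'
#' @param registry Registry tables.
#' @param variant Which sensitivity variant to run.
#' @param config,criteria As in [run_analysis()].
#' @return An `emul_analysis`.
#' @export
run_sensitivity <- function(registry,
                            variant = c("covariate_adjustment", "complete_case"),
                            config = analysis_config(),
                            criteria = eligibility_criteria()) {
  variant <- match.arg(variant)
  if (variant == "covariate_adjustment") {
    config$adjustment <- "covariate_in_model"
  } else {
    config$missing_handling <- "complete_case"
  }
  run_analysis(registry, config, criteria)
}
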