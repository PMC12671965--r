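# Synthetic linked-registry generator. Emulates the joint structure the
# analysis assumes: confounded choice of first endocrine therapy, a
# covariate-dependent discrete-time death hazard with a known conditional
# treatment effect, pharmacy dispensation streams with refill gaps, permanent
# stops and class switches, emigration, and administrative end of follow-up.

local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Solve the intercept so that mean(plogis(b + offset)) hits a target
# prevalence, then draw the flag. Deterministic given the offsets.
calibrated_flag <- function(target_p, offset) {
  n <- length(offset)
  if (n == 0) {
    return(integer(0))
  }
  if (target_p <= 0) {
    return(rep(0L, n))
  }
  b <- stats::uniroot(
    function(b) mean(plogis(b + offset)) - target_p,
    interval = c(-20, 20), tol = 1e-10
  )$root
  rbinom(n, 1, plogis(b + offset))
}

# Indicator/design columns the scenario coefficient maps refer to. The
# categorical covariates contribute through their observed levels, so a
# "missing" level contributes zero (reference) to every linear predictor.
scenario_design <- function(patients) {
  n <- nrow(patients)
  year <- as.integer(format(patients$.enroll_date, "%Y"))
  cbind(
    "(Intercept)" = rep(1, n),
    chemotherapy = patients$chemotherapy,
    radiotherapy = patients$radiotherapy,
    antibody = patients$antibody,
    stage2 = as.numeric(patients$stage == "2"),
    stage3 = as.numeric(patients$stage == "3"),
    t2 = as.numeric(patients$t_class == "T2"),
    t34 = as.numeric(patients$t_class == "T3/T4"),
    n1plus = as.numeric(patients$n_class == "N1+"),
    grade1 = as.numeric(patients$grade == "1"),
    grade3 = as.numeric(patients$grade == "3"),
    her2_positive = as.numeric(patients$her2 == "positive"),
    cerebrovascular_disease = patients$cerebrovascular_disease,
    diabetes = patients$diabetes,
    copd = patients$copd,
    cardiovascular_disease = patients$cardiovascular_disease,
    chronic_kidney_disease = patients$chronic_kidney_disease,
    diabetes_drugs = patients$diabetes_drugs,
    anticoagulants = patients$anticoagulants,
    antidepressants = patients$antidepressants,
    nsaids = patients$nsaids,
    opioids = patients$opioids,
    hormone_replacement_therapy = patients$hormone_replacement_therapy,
    age10 = (patients$age - 68) / 10,
    year_c = year - 2012
  )
}

linear_predictor <- function(design, coefs) {
  unknown <- setdiff(names(coefs), colnames(design))
  if (length(unknown)) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  drop(design[, names(coefs), drop = FALSE] %*% coefs)
}

comorbidity_names <- function() {
  c(
    "cerebrovascular_disease", "diabetes", "copd",
    "cardiovascular_disease", "chronic_kidney_disease"
  )
}

drug_group_names <- function() {
  c(
    "diabetes_drugs", "anticoagulants", "antidepressants",
    "nsaids", "opioids", "hormone_replacement_therapy"
  )
}

#' Generate a synthetic patient population with linked covariate tables
#'
#' Draws baseline demographics, tumour characteristics, adjuvant-treatment
#' flags, comorbidity and co-medication histories (with onset/fill dates),
#' socioeconomic categories with injected missingness, and the date spine
#' (diagnosis, surgery, intended first dispensation). Comorbidity and
#' co-medication flags share a latent patient-level factor so multimorbidity
#' clusters, mimicking the covariate mix of a registry population initiating
#' adjuvant endocrine therapy.
#'
#' @param config An [scenario_config()].
#' @return A list with tibbles `patients`, `diagnoses`
#'   (`patient_id`, `condition`, `date`) and `drug_covariates`
#'   (`patient_id`, `drug_group`, `date`). The patients table carries a
#'   generator-internal `.enroll_date` column (the intended first
#'   dispensation date) that downstream cohort construction ignores.
#' @export
generate_population <- function(config) {
  validate_scenario(config)
  n <- config$n_patients
  local_seed(config$seed, {
    z <- rnorm(n)
    age <- pmin(pmax(round(rnorm(n, 67.6, 8.5)), 40), 97)
    age10 <- (age - 68) / 10

    stage <- sample(c("1", "2", "3"), n, TRUE, prob = c(0.588, 0.384, 0.028))
    t_probs <- list(
      "1" = c(0.85, 0.15, 0.00),
      "2" = c(0.35, 0.55, 0.10),
      "3" = c(0.05, 0.45, 0.50)
    )
    n_probs <- c("1" = 0.98, "2" = 0.75, "3" = 0.10)
    t_class <- character(n)
    for (s in c("1", "2", "3")) {
      idx <- which(stage == s)
      t_class[idx] <- sample(c("T1", "T2", "T3/T4"), length(idx), TRUE,
        prob = t_probs[[s]]
      )
    }
    n_class <- ifelse(runif(n) < n_probs[stage], "N0", "N1+")
    grade <- sample(c("1", "2", "3"), n, TRUE, prob = c(0.20, 0.57, 0.23))
    her2 <- sample(c("positive", "negative"), n, TRUE, prob = c(0.092, 0.908))
    side <- sample(c("right", "left"), n, TRUE, prob = c(0.481, 0.519))

    chemo_offset <- 1.6 * (stage == "2") + 3.2 * (stage == "3") +
      1.4 * (n_class == "N1+") + 1.5 * (her2 == "positive") +
      1.0 * (grade == "3") - 0.5 * age10
    chemotherapy <- calibrated_flag(0.216, chemo_offset)
    radiotherapy <- calibrated_flag(0.222, 0.3 * (n_class == "N1+"))
    antibody <- ifelse(her2 == "positive", rbinom(n, 1, 0.60), rbinom(n, 1, 0.005))

    cc <- config$comorbidity_cor
    com_targets <- c(
      cerebrovascular_disease = 0.021, diabetes = 0.061, copd = 0.027,
      cardiovascular_disease = 0.343, chronic_kidney_disease = 0.020
    )
    com_age <- c(
      cerebrovascular_disease = 0.8, diabetes = 0.4, copd = 0.3,
      cardiovascular_disease = 0.9, chronic_kidney_disease = 0.8
    )
    com <- lapply(names(com_targets), function(nm) {
      calibrated_flag(com_targets[[nm]], cc * z + com_age[[nm]] * age10)
    })
    names(com) <- names(com_targets)

    diabetes_drugs <- ifelse(com$diabetes == 1, rbinom(n, 1, 0.85),
      rbinom(n, 1, 0.01)
    )
    drug_targets <- c(
      anticoagulants = 0.269, antidepressants = 0.190,
      nsaids = 0.405, opioids = 0.301, hormone_replacement_therapy = 0.322
    )
    drug_age <- c(
      anticoagulants = 0.8, antidepressants = 0.0, nsaids = 0.0,
      opioids = 0.2, hormone_replacement_therapy = -0.3
    )
    dr <- lapply(names(drug_targets), function(nm) {
      calibrated_flag(drug_targets[[nm]], cc * z + drug_age[[nm]] * age10)
    })
    names(dr) <- names(drug_targets)

    marital <- sample(c("single", "married_cohabiting", "divorced_widowed"),
      n, TRUE,
      prob = c(0.124, 0.591, 0.285)
    )
    education <- sample(c("pre_secondary", "high_school", "post_secondary"),
      n, TRUE,
      prob = c(0.281, 0.414, 0.305)
    )
    employment <- sample(c("employed", "not_employed"), n, TRUE,
      prob = c(0.561, 0.439)
    )

    mr <- config$missing_rates
    inject <- function(x, rate) {
      x[runif(length(x)) < rate] <- "missing"
      x
    }
    grade <- inject(grade, mr[["grade"]])
    her2 <- inject(her2, mr[["her2"]])
    education <- inject(education, mr[["education"]])
    employment <- inject(employment, mr[["employment"]])

    window_days <- as.numeric(config$admin_end - config$enrollment_start)
    enroll <- config$enrollment_start + floor(runif(n, 0, window_days + 1))
    disp_delay <- ifelse(
      chemotherapy == 1,
      pmin(pmax(round(rgamma(n, shape = 10, scale = 12)), 60), 270),
      pmin(pmax(round(rgamma(n, shape = 4, scale = 11)), 7), 250)
    )
    disp_delay <- pmin(disp_delay + 25 * (stage == "2") + 50 * (stage == "3"), 272)
    surg_delay <- round(runif(n, 12, 30))
    surgery_date <- enroll - disp_delay
    diagnosis_date <- surgery_date - surg_delay

    patients <- tibble::tibble(
      patient_id = sprintf("P%06d", seq_len(n)),
      sex = rep("female", n),
      age = as.numeric(age),
      diagnosis_date = diagnosis_date,
      surgery_date = surgery_date,
      clear_margins = rbinom(n, 1, config$margin_clear_prob) == 1,
      hr_positive = rep(TRUE, n),
      postmenopausal = rep(TRUE, n),
      prior_malignancy = rep(FALSE, n),
      bilateral = rep(FALSE, n),
      stage = stage, t_class = t_class, n_class = n_class,
      grade = grade, her2 = her2, side = side,
      chemotherapy = as.numeric(chemotherapy),
      radiotherapy = as.numeric(radiotherapy),
      antibody = as.numeric(antibody),
      cerebrovascular_disease = as.numeric(com$cerebrovascular_disease),
      diabetes = as.numeric(com$diabetes),
      copd = as.numeric(com$copd),
      cardiovascular_disease = as.numeric(com$cardiovascular_disease),
      chronic_kidney_disease = as.numeric(com$chronic_kidney_disease),
      diabetes_drugs = as.numeric(diabetes_drugs),
      anticoagulants = as.numeric(dr$anticoagulants),
      antidepressants = as.numeric(dr$antidepressants),
      nsaids = as.numeric(dr$nsaids),
      opioids = as.numeric(dr$opioids),
      hormone_replacement_therapy = as.numeric(dr$hormone_replacement_therapy),
      marital = marital, education = education, employment = employment,
      death_date = as.Date(rep(NA, n)),
      emigration_date = as.Date(rep(NA, n)),
      .enroll_date = enroll
    )

    diagnoses <- make_diagnoses(patients, config)
    drug_covariates <- make_drug_covariates(patients, config)
    list(
      patients = patients,
      diagnoses = diagnoses,
      drug_covariates = drug_covariates
    )
  })
}

# Diagnosis records: one prevalent record before baseline for each baseline
# comorbidity flag, plus incident onsets during follow-up at small monthly
# rates (flags are monotone thereafter).
make_diagnoses <- function(patients, config) {
  n <- nrow(patients)
  inc_rate <- c(
    cerebrovascular_disease = 8e-4, diabetes = 1.2e-3, copd = 8e-4,
    cardiovascular_disease = 3e-3, chronic_kidney_disease = 8e-4
  )
  rows <- list()
  for (cond in comorbidity_names()) {
    flag <- patients[[cond]] == 1
    if (any(flag)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = patients$patient_id[flag],
        condition = cond,
        date = patients$.enroll_date[flag] -
          round(runif(sum(flag), 183, 3650))
      )
    }
    # incident onsets among the unaffected
    idx <- which(!flag)
    if (length(idx)) {
      m_first <- rgeom(length(idx), inc_rate[[cond]])
      hit <- m_first < config$max_months
      if (any(hit)) {
        day <- floor(m_first[hit] * config$interval_days +
          runif(sum(hit), 1, config$interval_days))
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = patients$patient_id[idx[hit]],
          condition = cond,
          date = patients$.enroll_date[idx[hit]] + day
        )
      }
    }
  }
  out <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$date)
  } else {
    tibble::tibble(
      patient_id = character(), condition = character(),
      date = as.Date(character())
    )
  }
  out
}

# Co-medication fills: baseline users have a fill inside the 183-day
# lookback and keep refilling about every 90 days with per-fill persistence;
# non-users may initiate during follow-up.
make_drug_covariates <- function(patients, config) {
  n <- nrow(patients)
  horizon <- config$max_months * config$interval_days
  rows <- list()
  for (grp in drug_group_names()) {
    user <- patients[[grp]] == 1
    idx_u <- which(user)
    if (length(idx_u)) {
      # fill inside the baseline lookback window
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = patients$patient_id[idx_u],
        drug_group = grp,
        date = patients$.enroll_date[idx_u] - round(runif(length(idx_u), 1, 180))
      )
      # refills after baseline: geometric number of ~90-day cycles
      n_fills <- pmin(rgeom(length(idx_u), 0.10), 25)
      reps <- rep(seq_along(idx_u), n_fills)
      if (length(reps)) {
        fill_no <- sequence(n_fills[n_fills > 0])
        day <- fill_no * 90 + round(runif(length(reps), -15, 15))
        keep <- day >= 1 & day <= horizon
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = patients$patient_id[idx_u][reps][keep],
          drug_group = grp,
          date = patients$.enroll_date[idx_u][reps][keep] + day[keep]
        )
      }
    }
    idx_n <- which(!user)
    if (length(idx_n)) {
      m_first <- rgeom(length(idx_n), 2e-3)
      hit <- m_first < config$max_months
      if (any(hit)) {
        day <- floor(m_first[hit] * config$interval_days +
          runif(sum(hit), 1, config$interval_days))
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = patients$patient_id[idx_n[hit]],
          drug_group = grp,
          date = patients$.enroll_date[idx_n[hit]] + day
        )
      }
    }
  }
  out <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$date)
  } else {
    tibble::tibble(
      patient_id = character(), drug_group = character(),
      date = as.Date(character())
    )
  }
  out
}

#' Generate endocrine dispensation streams
#'
#' Chooses each patient's first-fill drug class from a logistic model on the
#' baseline covariates (`treatment_model_coefs`), then simulates a refill
#' stream: supply per fill from the pill count times strength over the
#' defined daily dose, prompt or delayed refills, permanent stops at the
#' per-arm discontinuation hazard, and (at most one) switch to the other
#' drug class. Fills stop at the administrative end of follow-up.
#'
#' @param population Output of [generate_population()], or its `patients`
#'   tibble together with `config`.
#' @param config An [scenario_config()].
#' @return A list with `dispensations` (`patient_id`, `drug`, `date`,
#'   `pills`, `strength`) and `assignments` (`patient_id`, `first_class`,
#'   `switch_day`, `stop_day` in days since first fill; `NA` when absent).
#' @export
generate_dispensations <- function(population, config) {
  validate_scenario(config)
  patients <- if (is.data.frame(population)) population else population$patients
  n <- nrow(patients)
  dict <- ddd_table()
  ap <- config$adherence_params

  empty <- list(
    dispensations = tibble::tibble(
      patient_id = character(), drug = character(), date = as.Date(character()),
      pills = numeric(), strength = numeric()
    ),
    assignments = tibble::tibble(
      patient_id = character(), first_class = character(),
      switch_day = numeric(), stop_day = numeric()
    )
  )
  if (n == 0) {
    return(empty)
  }

  local_seed(config$seed + 1L, {
    design <- scenario_design(patients)
    p_ai <- plogis(linear_predictor(design, config$treatment_model_coefs))
    first_class <- ifelse(runif(n) < p_ai, "aromatase_inhibitor", "tamoxifen")

    pick_drug <- function(cls) {
      ai <- cls == "aromatase_inhibitor"
      out <- rep("tamoxifen", length(cls))
      if (any(ai)) {
        out[ai] <- sample(c("letrozole", "anastrozole", "exemestane"),
          sum(ai), TRUE,
          prob = c(0.55, 0.35, 0.10)
        )
      }
      out
    }

    disc_monthly <- ifelse(first_class == "aromatase_inhibitor",
      ap$disc_hazard_ai, ap$disc_hazard_tam
    )
    if (!is.null(ap$disc_model_coefs)) {
      eta <- linear_predictor(
        design,
        ap$disc_model_coefs[setdiff(names(ap$disc_model_coefs), "(Intercept)")]
      )
      disc_monthly <- plogis(qlogis(pmax(disc_monthly, 1e-12)) + eta)
      disc_monthly[ap$disc_hazard_ai == 0 & first_class == "aromatase_inhibitor"] <- 0
      disc_monthly[ap$disc_hazard_tam == 0 & first_class != "aromatase_inhibitor"] <- 0
    }

    horizon <- pmin(
      as.numeric(config$admin_end - patients$.enroll_date),
      config$max_months * config$interval_days + 90
    )

    cur_class <- first_class
    cur_drug <- pick_drug(first_class)
    cur_day <- rep(0, n)
    active <- rep(TRUE, n)
    can_switch <- rep(TRUE, n)
    switch_day <- rep(NA_real_, n)
    stop_day <- rep(NA_real_, n)
    out <- vector("list", 80)
    it <- 0L

    while (any(active) && it < 80L) {
      it <- it + 1L
      idx <- which(active)
      drug <- cur_drug[idx]
      di <- match(drug, dict$drug)
      pills <- unlist(config$supply[drug], use.names = FALSE)
      strength <- dict$strength_mg[di]
      dur <- pmax(round(pills * strength / dict$ddd_mg[di]), 1)
      out[[it]] <- tibble::tibble(
        patient_id = patients$patient_id[idx],
        drug = drug,
        date = patients$.enroll_date[idx] + cur_day[idx],
        pills = pills,
        strength = strength
      )
      covered <- cur_day[idx] + dur

      p_fill_disc <- 1 - (1 - disc_monthly[idx])^(dur / config$interval_days)
      stops <- runif(length(idx)) < p_fill_disc
      switches <- stops & can_switch[idx] & runif(length(idx)) < ap$p_switch

      # permanent stop: exposure ends when the last supply runs out
      perm <- idx[stops & !switches]
      stop_day[perm] <- covered[stops & !switches]
      active[perm] <- FALSE

      # switch: the other class is started at the next scheduled fill date
      sw <- idx[switches]
      if (length(sw)) {
        cur_class[sw] <- ifelse(cur_class[sw] == "aromatase_inhibitor",
          "tamoxifen", "aromatase_inhibitor"
        )
        cur_drug[sw] <- pick_drug(cur_class[sw])
        can_switch[sw] <- FALSE
        nd <- covered[switches] + round(rexp(length(sw), 1 / 10))
        cur_day[sw] <- nd
        switch_day[sw] <- nd
      }

      # continue on the same drug, prompt or delayed refill
      cont <- idx[!stops]
      if (length(cont)) {
        prompt <- runif(length(cont)) < ap$p_prompt_refill
        delay <- ifelse(prompt, 0, round(rexp(
          length(cont),
          1 / max(ap$refill_delay_mean, 1e-9)
        )))
        cur_day[cont] <- covered[!stops] + delay
      }

      past <- which(active & cur_day > horizon)
      active[past] <- FALSE
    }

    dispensations <- dplyr::arrange(
      dplyr::bind_rows(out[seq_len(it)]),
      .data$patient_id, .data$date
    )
    assignments <- tibble::tibble(
      patient_id = patients$patient_id,
      first_class = first_class,
      switch_day = switch_day,
      stop_day = stop_day
    )
    list(dispensations = dispensations, assignments = assignments)
  })
}

# Exposure indicator used by the death hazard: currently supplied with an
# aromatase inhibitor at the given day since first fill.
on_ai_at <- function(assignments, day) {
  cls <- assignments$first_class
  switched <- !is.na(assignments$switch_day) & day >= assignments$switch_day
  cls[switched] <- ifelse(cls[switched] == "aromatase_inhibitor",
    "tamoxifen", "aromatase_inhibitor"
  )
  stopped <- !is.na(assignments$stop_day) & day >= assignments$stop_day
  cls == "aromatase_inhibitor" & !stopped
}

#' Simulate death and emigration
#'
#' Walks the discrete monthly clock: in each interval every patient still
#' alive and in the country faces a death probability from the logistic
#' hazard on baseline covariates plus the conditional treatment effect for
#' months currently covered by an aromatase inhibitor, and an independent
#' emigration probability. Death within an interval pre-empts emigration.
#'
#' @param patients Patients tibble from [generate_population()].
#' @param assignments Assignments tibble from [generate_dispensations()].
#' @param config An [scenario_config()].
#' @return The patients tibble with `death_date`, `emigration_date` and
#'   `vital_status` filled in.
#' @export
generate_outcomes <- function(patients, assignments, config) {
  validate_scenario(config)
  n <- nrow(patients)
  if (n == 0) {
    return(dplyr::mutate(patients, vital_status = character(0)))
  }
  stopifnot(identical(patients$patient_id, assignments$patient_id))
  local_seed(config$seed + 2L, {
    design <- scenario_design(patients)
    eta0 <- linear_predictor(design, config$hazard_model_coefs)
    death_day <- rep(NA_real_, n)
    emig_day <- rep(NA_real_, n)
    at_risk <- rep(TRUE, n)
    iv <- config$interval_days
    for (m in seq_len(config$max_months) - 1L) {
      idx <- which(at_risk)
      if (!length(idx)) break
      on_ai <- on_ai_at(assignments[idx, ], (m + 0.5) * iv)
      h <- plogis(eta0[idx] + config$true_treatment_log_or * on_ai)
      dies <- runif(length(idx)) < h
      dd <- idx[dies]
      if (length(dd)) {
        death_day[dd] <- floor(runif(length(dd), m * iv, (m + 1) * iv - 1e-9))
        at_risk[dd] <- FALSE
      }
      rest <- idx[!dies]
      if (length(rest) && config$emigration_rate > 0) {
        emig <- runif(length(rest)) < config$emigration_rate
        ee <- rest[emig]
        if (length(ee)) {
          emig_day[ee] <- floor(runif(length(ee), m * iv, (m + 1) * iv - 1e-9))
          at_risk[ee] <- FALSE
        }
      }
    }
    patients$death_date <- patients$.enroll_date + death_day
    patients$emigration_date <- patients$.enroll_date + emig_day
    patients$vital_status <- ifelse(is.na(death_day), "alive", "dead")
    patients
  })
}

#' Simulate a full linked synthetic registry
#'
#' Convenience wrapper chaining [generate_population()],
#' [generate_dispensations()] and [generate_outcomes()], and truncating all
#' record streams at death. Deterministic: the same config (including its
#' seed) yields byte-identical tables.
#'
#' @param config An [scenario_config()].
#' @return A list of class `emul_registry` with tibbles `patients`,
#'   `dispensations`, `diagnoses`, `drug_covariates` and the
#'   generator-truth `assignments`.
#' @export
#' @examples
#' reg <- simulate_registry(scenario_config(n_patients = 200, seed = 42))
#' reg$patients
simulate_registry <- function(config) {
  pop <- generate_population(config)
  ds <- generate_dispensations(pop$patients, config)
  patients <- generate_outcomes(pop$patients, ds$assignments, config)

  trunc_at_death <- function(tbl) {
    dd <- patients$death_date[match(tbl$patient_id, patients$patient_id)]
    tbl[is.na(dd) | tbl$date <= dd, , drop = FALSE]
  }
  structure(
    list(
      patients = patients,
      dispensations = trunc_at_death(ds$dispensations),
      diagnoses = trunc_at_death(pop$diagnoses),
      drug_covariates = trunc_at_death(pop$drug_covariates),
      assignments = ds$assignments
    ),
    class = "emul_registry"
  )
}

#' @export
print.emul_registry <- function(x, ...) {
  cat(
    "<emul_registry> ", nrow(x$patients), " patients, ",
    nrow(x$dispensations), " dispensations, ",
    nrow(x$diagnoses), " diagnosis records, ",
    nrow(x$drug_covariates), " co-medication fills\n",
    sep = ""
  )
  invisible(x)
}

#' True counterfactual 5-year risks for a scenario
#'
#' Computes the standardized counterfactual risks the estimators target:
#' for every generated patient the exact 5-year death risk under sustained
#' aromatase-inhibitor and sustained tamoxifen treatment (no confounding, no
#' nonadherence, no censoring), averaged over the population. Because the
#' per-patient risk is available in closed form from the discrete hazard,
#' the only Monte Carlo error is over the covariate draw, and the reported
#' standard errors shrink as 1/sqrt(n_mc).
#'
#' @param config An [scenario_config()].
#' @param n_mc Number of patients to draw (defaults to `config$n_patients`).
#' @return A list of class `emul_truth` with elements `risk_ai_5y`,
#'   `risk_tam_5y`, `true_rd` (risk difference, probability scale),
#'   `true_rr`, `mc_se` (standard errors for the three risk quantities) and
#'   `n_mc`.
#' @export
true_counterfactual_risks <- function(config, n_mc = config$n_patients) {
  validate_scenario(config)
  n_mc <- as.integer(n_mc)
  if (is.na(n_mc) || n_mc < 1) {
    stop("n_mc must be a positive integer", call. = FALSE)
  }
  cfg <- config
  cfg$n_patients <- n_mc
  pop <- generate_population(cfg)
  design <- scenario_design(pop$patients)
  eta0 <- linear_predictor(design, config$hazard_model_coefs)
  K <- config$max_months
  risk_under <- function(a) {
    h <- plogis(eta0 + a * config$true_treatment_log_or)
    1 - (1 - h)^K
  }
  r1 <- risk_under(1)
  r0 <- risk_under(0)
  structure(
    list(
      risk_ai_5y = mean(r1),
      risk_tam_5y = mean(r0),
      true_rd = mean(r1 - r0),
      true_rr = mean(r1) / mean(r0),
      mc_se = c(
        risk_ai = sd(r1) / sqrt(n_mc),
        risk_tam = sd(r0) / sqrt(n_mc),
        rd = sd(r1 - r0) / sqrt(n_mc)
      ),
      n_mc = n_mc
    ),
    class = "emul_truth"
  )
}

#' @export
print.emul_truth <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<emul_truth> counterfactual 5-year risks (n_mc = %d)\n",
      "  aromatase inhibitor: %.4f\n  tamoxifen:           %.4f\n",
      "  risk difference:     %+.4f (MC SE %.5f)\n  risk ratio:          %.3f\n"
    ),
    x$n_mc, x$risk_ai_5y, x$risk_tam_5y, x$true_rd, x$mc_se[["rd"]], x$true_rr
  ))
  invisible(x)
}
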