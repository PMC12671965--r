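# Cohort construction: eligibility screening, strategy assignment from the
# first endocrine dispensation, and baseline covariate assembly.

#' Eligibility criteria configuration
#'
#' @param min_age Minimum age (years) at baseline.
#' @param postmenopausal_age Age at diagnosis taken as a postmenopausal
#'   proxy; a `postmenopausal` flag column, when present, also qualifies.
#' @param max_surgery_to_disp_days Maximum days between primary surgery and
#'   first endocrine dispensation ("within 9 months" = 274 days).
#' @param enrollment_start,admin_end Study window for the first
#'   dispensation; `admin_end` is also the administrative end of follow-up.
#' @param max_months Follow-up horizon in months.
#' @param interval_days Days per discrete follow-up interval.
#' @return A list of class `emul_criteria`.
#' @export
eligibility_criteria <- function(min_age = 40,
                                 postmenopausal_age = 50,
                                 max_surgery_to_disp_days = 274,
                                 enrollment_start = as.Date("2009-08-01"),
                                 admin_end = as.Date("2015-12-31"),
                                 max_months = 60L,
                                 interval_days = 30.4375) {
  structure(
    list(
      min_age = min_age,
      postmenopausal_age = postmenopausal_age,
      max_surgery_to_disp_days = max_surgery_to_disp_days,
      enrollment_start = as.Date(enrollment_start),
      admin_end = as.Date(admin_end),
      max_months = as.integer(max_months),
      interval_days = interval_days
    ),
    class = "emul_criteria"
  )
}

require_columns <- function(tbl, cols, what) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss)) {
    stop(
      what, " is missing required column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(tbl)
}

# First endocrine fill per patient: defines baseline date and assigned
# strategy; flags patients whose first-day fills span both drug classes.
first_endocrine_fill <- function(dispensations) {
  require_columns(
    dispensations, c("patient_id", "drug", "date"),
    "dispensation table"
  )
  d <- dispensations[dispensations$drug %in% endocrine_drugs(), , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(
      patient_id = character(), baseline_date = as.Date(character()),
      strategy = character(), ambiguous = logical()
    ))
  }
  d$drug_class <- drug_class_of(d$drug)
  d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      baseline_date = min(.data$date),
      strategy = .data$drug_class[which.min(.data$date)],
      ambiguous = dplyr::n_distinct(
        .data$drug_class[.data$date == min(.data$date)]
      ) > 1L,
      .groups = "drop"
    )
}

#' Apply the emulation's eligibility criteria
#'
#' Screens the patient table against each criterion in a fixed order and
#' records the number removed per criterion in an exclusion ledger
#' (selection-flowchart analogue). Baseline is the first endocrine
#' dispensation; criteria that need it (study window, time since surgery,
#' age at baseline) are evaluated at that date.
#'
#' @param patients Patient table.
#' @param dispensations Dispensation table.
#' @param criteria An [eligibility_criteria()].
#' @return A list with `eligible` (patients joined with `baseline_date` and
#'   `strategy`) and `ledger` (tibble of `criterion`, `n_removed`, plus a
#'   final `eligible` row).
#' @export
apply_eligibility <- function(patients, dispensations,
                              criteria = eligibility_criteria()) {
  require_columns(
    patients,
    c(
      "patient_id", "sex", "age", "diagnosis_date", "surgery_date",
      "clear_margins", "hr_positive", "stage", "prior_malignancy", "bilateral"
    ),
    "patient table"
  )
  ff <- first_endocrine_fill(dispensations)
  pool <- dplyr::left_join(patients, ff, by = "patient_id")

  ledger <- list()
  drop_if <- function(pool, criterion, bad) {
    bad[is.na(bad)] <- TRUE
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      criterion = criterion, n_removed = sum(bad)
    )
    pool[!bad, , drop = FALSE]
  }

  age_at_dx <- pool$age -
    as.numeric(pool$baseline_date - pool$diagnosis_date) / 365.25
  postmeno_flag <- if ("postmenopausal" %in% names(pool)) {
    pool$postmenopausal
  } else {
    FALSE
  }
  pool$._postmeno <- (!is.na(age_at_dx) &
    age_at_dx >= criteria$postmenopausal_age) | postmeno_flag

  pool <- drop_if(pool, "not_female", pool$sex != "female")
  pool <- drop_if(pool, "not_hormone_receptor_positive", !pool$hr_positive)
  pool <- drop_if(
    pool, "stage_not_1_to_3",
    !(pool$stage %in% c("1", "2", "3"))
  )
  pool <- drop_if(
    pool, "no_surgery_with_clear_margins",
    is.na(pool$surgery_date) | !pool$clear_margins
  )
  pool <- drop_if(pool, "prior_malignancy", pool$prior_malignancy)
  pool <- drop_if(pool, "bilateral_breast_cancer", pool$bilateral)
  pool <- drop_if(
    pool, "no_endocrine_dispensation",
    is.na(pool$baseline_date)
  )
  pool <- drop_if(
    pool, "first_dispensation_outside_study_window",
    pool$baseline_date < criteria$enrollment_start |
      pool$baseline_date > criteria$admin_end
  )
  gap <- as.numeric(pool$baseline_date - pool$surgery_date)
  pool <- drop_if(
    pool, "first_dispensation_not_within_9_months_of_surgery",
    gap < 0 | gap > criteria$max_surgery_to_disp_days
  )
  pool <- drop_if(
    pool, sprintf("age_under_%d", criteria$min_age),
    pool$age < criteria$min_age
  )
  pool <- drop_if(pool, "not_postmenopausal", !pool$._postmeno)
  pool <- drop_if(pool, "ambiguous_first_fill", pool$ambiguous)
  pool$._postmeno <- NULL

  ledger <- dplyr::bind_rows(ledger)
  ledger <- dplyr::bind_rows(
    ledger,
    tibble::tibble(criterion = "eligible", n_removed = NA_integer_)
  )
  ledger$n_remaining <- c(
    nrow(patients) - cumsum(ledger$n_removed[-nrow(ledger)]),
    nrow(pool)
  )
  list(eligible = pool, ledger = ledger)
}

#' Assign the treatment strategy from the first dispensation
#'
#' Strategy is `aromatase_inhibitor` when the earliest endocrine fill is
#' letrozole, anastrozole or exemestane, `tamoxifen` otherwise; baseline is
#' that fill's date. Patients whose first-day fills span both classes have
#' no defined strategy and are dropped (with a message); patients without
#' any endocrine fill are likewise dropped, mirroring eligibility.
#'
#' @param patients Patient table (any table with `patient_id`).
#' @param dispensations Dispensation table.
#' @return `patients` joined with `strategy` and `baseline_date`.
#' @export
assign_strategy <- function(patients, dispensations) {
  ff <- first_endocrine_fill(dispensations)
  n_amb <- sum(ff$ambiguous)
  if (n_amb > 0) {
    message(n_amb, " patient(s) with same-day first fills of both classes dropped")
  }
  ff <- ff[!ff$ambiguous, c("patient_id", "strategy", "baseline_date")]
  out <- dplyr::inner_join(
    patients[setdiff(names(patients), c("strategy", "baseline_date", "ambiguous"))],
    ff,
    by = "patient_id"
  )
  out
}

#' Baseline covariate roster
#'
#' Names of the baseline covariates entering the treatment-weight model and
#' the covariate-adjusted sensitivity model: demographics, tumour
#' characteristics, adjuvant treatments, comorbidity and co-medication
#' flags, and socioeconomic categories.
#'
#' @return Character vector of column names in the assembled cohort.
#' @export
baseline_covariate_names <- function() {
  c(
    "age", "year", "time_from_diagnosis", "stage", "t_class", "n_class",
    "grade", "her2", "side", "chemotherapy", "radiotherapy", "antibody",
    "cerebrovascular_disease", "diabetes", "copd", "cardiovascular_disease",
    "diabetes_drugs", "anticoagulants", "antidepressants", "nsaids",
    "opioids", "hormone_replacement_therapy", "marital", "education",
    "employment"
  )
}

time_varying_covariate_names <- function() {
  c(
    "cerebrovascular_disease", "diabetes", "copd", "cardiovascular_disease",
    "chronic_kidney_disease", "diabetes_drugs", "anticoagulants",
    "antidepressants", "nsaids", "opioids", "hormone_replacement_therapy"
  )
}

factor_levels <- function() {
  list(
    stage = c("1", "2", "3"),
    t_class = c("T1", "T2", "T3/T4"),
    n_class = c("N0", "N1+"),
    grade = c("2", "1", "3", "missing"),
    her2 = c("negative", "positive", "missing"),
    side = c("right", "left"),
    marital = c("married_cohabiting", "single", "divorced_widowed", "missing"),
    education = c("high_school", "pre_secondary", "post_secondary", "missing"),
    employment = c("employed", "not_employed", "missing")
  )
}

as_missing_factor <- function(x, levels, name) {
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop(
      "unexpected level(s) in ", name, ": ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  factor(x, levels = levels)
}

# Binary history flag: any qualifying record inside (baseline - window,
# baseline]. Window Inf means all available history.
history_flag <- function(keys, records, key_col, window_days) {
  if (nrow(records) == 0) {
    return(rep(0, nrow(keys)))
  }
  rec <- dplyr::inner_join(
    records,
    keys[c("patient_id", "baseline_date")],
    by = "patient_id"
  )
  dt <- as.numeric(rec$baseline_date - rec$date)
  hit <- rec$patient_id[dt >= 0 & dt < window_days | (is.infinite(window_days) & dt >= 0)]
  as.numeric(keys$patient_id %in% hit)
}

#' Assemble the baseline covariate vector
#'
#' Builds the analysis covariates at baseline: continuous covariates (age,
#' time from diagnosis in whole days), calendar year of baseline,
#' categorical tumour and socioeconomic covariates with an explicit
#' `"missing"` level, and binary comorbidity and co-medication flags from
#' qualifying records on or before baseline. Comorbidity lookback defaults
#' to all available history; co-medication lookback to 183 days. Records
#' after baseline are never consulted.
#'
#' @param eligible Eligible patients with `baseline_date` and `strategy`
#'   (from [apply_eligibility()] / [assign_strategy()]).
#' @param diagnoses Diagnosis table (`patient_id`, `condition`, `date`).
#' @param drug_covariates Co-medication table (`patient_id`, `drug_group`,
#'   `date`).
#' @param comorbidity_lookback_days,drug_lookback_days Lookback windows.
#' @return Cohort tibble: identifiers, `baseline_date`, `strategy`, the
#'   covariates of [baseline_covariate_names()] plus
#'   `chronic_kidney_disease`, and the event dates carried through.
#' @export
assemble_baseline_covariates <- function(eligible, diagnoses, drug_covariates,
                                         comorbidity_lookback_days = Inf,
                                         drug_lookback_days = 183) {
  require_columns(
    eligible, c("patient_id", "baseline_date", "strategy", "age"),
    "eligible table"
  )
  lv <- factor_levels()
  out <- tibble::tibble(
    patient_id = eligible$patient_id,
    baseline_date = eligible$baseline_date,
    strategy = eligible$strategy,
    age = eligible$age,
    year = factor(format(eligible$baseline_date, "%Y")),
    time_from_diagnosis = as.numeric(
      eligible$baseline_date - eligible$diagnosis_date
    ),
    stage = as_missing_factor(eligible$stage, lv$stage, "stage"),
    t_class = as_missing_factor(eligible$t_class, lv$t_class, "t_class"),
    n_class = as_missing_factor(eligible$n_class, lv$n_class, "n_class"),
    grade = as_missing_factor(eligible$grade, lv$grade, "grade"),
    her2 = as_missing_factor(eligible$her2, lv$her2, "her2"),
    side = as_missing_factor(eligible$side, lv$side, "side"),
    chemotherapy = as.numeric(eligible$chemotherapy),
    radiotherapy = as.numeric(eligible$radiotherapy),
    antibody = as.numeric(eligible$antibody),
    marital = as_missing_factor(eligible$marital, lv$marital, "marital"),
    education = as_missing_factor(eligible$education, lv$education, "education"),
    employment = as_missing_factor(
      eligible$employment, lv$employment, "employment"
    )
  )
  for (cond in comorbidity_names()) {
    rec <- diagnoses[diagnoses$condition == cond, , drop = FALSE]
    out[[cond]] <- history_flag(out, rec, "condition", comorbidity_lookback_days)
  }
  for (grp in drug_group_names()) {
    rec <- drug_covariates[drug_covariates$drug_group == grp, , drop = FALSE]
    out[[grp]] <- history_flag(out, rec, "drug_group", drug_lookback_days)
  }
  carry <- intersect(
    c("death_date", "emigration_date", "surgery_date", "diagnosis_date"),
    names(eligible)
  )
  dplyr::bind_cols(out, eligible[carry])
}

#' Build the analysis cohort from registry tables
#'
#' Runs eligibility screening, strategy assignment and covariate assembly,
#' then attaches each patient's follow-up end: the first of death,
#' emigration, 5 years since baseline, or the administrative end of
#' follow-up.
#'
#' @param registry A list with `patients`, `dispensations`, `diagnoses`,
#'   `drug_covariates` (e.g. from [simulate_registry()] or
#'   [read_registry()]).
#' @param criteria An [eligibility_criteria()].
#' @param comorbidity_lookback_days,drug_lookback_days Passed to
#'   [assemble_baseline_covariates()].
#' @return The cohort tibble with columns `followup_end_date` and
#'   `end_reason`, and the exclusion ledger in attribute
#'   `"exclusion_ledger"` (see [exclusion_ledger()]).
#' @export
#' @examples
#' reg <- simulate_registry(scenario_config(n_patients = 150, seed = 9))
#' cohort <- build_cohort(reg)
#' exclusion_ledger(cohort)
build_cohort <- function(registry, criteria = eligibility_criteria(),
                         comorbidity_lookback_days = Inf,
                         drug_lookback_days = 183) {
  elig <- apply_eligibility(registry$patients, registry$dispensations, criteria)
  cohort <- assemble_baseline_covariates(
    elig$eligible, registry$diagnoses, registry$drug_covariates,
    comorbidity_lookback_days = comorbidity_lookback_days,
    drug_lookback_days = drug_lookback_days
  )

  horizon_days <- floor(criteria$max_months * criteria$interval_days)
  five_years <- cohort$baseline_date + horizon_days
  cand <- cbind(
    death = as.numeric(cohort$death_date),
    emigration = as.numeric(cohort$emigration_date),
    five_years = as.numeric(five_years),
    admin_end = as.numeric(rep(criteria$admin_end, nrow(cohort)))
  )
  # first-occurring event; column order breaks ties (death first)
  reason_idx <- apply(cand, 1, function(r) which.min(r))
  end_num <- cand[cbind(seq_len(nrow(cand)), reason_idx)]
  if (nrow(cohort) == 0) {
    cohort$followup_end_date <- as.Date(character())
    cohort$end_reason <- character()
  } else {
    cohort$followup_end_date <- as.Date(end_num, origin = "1970-01-01")
    cohort$end_reason <- colnames(cand)[reason_idx]
  }
  if (any(cohort$followup_end_date < cohort$baseline_date, na.rm = TRUE)) {
    stop("death or emigration before baseline in input data", call. = FALSE)
  }
  attr(cohort, "exclusion_ledger") <- elig$ledger
  attr(cohort, "criteria") <- criteria
  cohort
}

#' @rdname build_cohort
#' @param cohort A cohort built by [build_cohort()].
#' @export
exclusion_ledger <- function(cohort) {
  attr(cohort, "exclusion_ledger")
}
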