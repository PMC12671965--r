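# Discrete person-period expansion: one record per patient-month carrying
# the event indicator, censoring markers, and time-varying covariate flags.

#' Expand the cohort into discrete person-period records
#'
#' One record per patient per follow-up interval (default 1 month =
#' 30.4375 days), 0-based index `k`. Death is assigned to the interval
#' containing the death date (`Y_k = 1` on the last record); follow-up is
#' truncated at `max_months` and at the administrative end (the partially
#' observed final interval is retained); the interval containing an
#' emigration date is dropped.
#'
#' @param cohort Cohort from [build_cohort()] (needs `baseline_date`,
#'   `followup_end_date`, `end_reason`, `strategy`).
#' @param interval_days Days per interval.
#' @param max_months Follow-up horizon in intervals.
#' @return Tibble `patient_id`, `strategy`, `k`, `Y_k`.
#' @export
expand_person_periods <- function(cohort, interval_days = 30.4375,
                                  max_months = 60L) {
  require_columns(
    cohort,
    c("patient_id", "baseline_date", "followup_end_date", "end_reason", "strategy"),
    "cohort"
  )
  fu_days <- as.numeric(cohort$followup_end_date - cohort$baseline_date)
  if (any(fu_days < 0)) {
    stop("follow-up end before baseline", call. = FALSE)
  }
  n_int <- integer(nrow(cohort))
  death <- cohort$end_reason == "death"
  emig <- cohort$end_reason == "emigration"
  other <- !death & !emig
  n_int[death] <- pmin(floor(fu_days[death] / interval_days), max_months - 1) + 1L
  n_int[emig] <- pmin(floor(fu_days[emig] / interval_days), max_months)
  n_int[other] <- pmin(ceiling(fu_days[other] / interval_days), max_months)

  keep <- n_int > 0L
  idx <- rep(which(keep), n_int[keep])
  k <- sequence(n_int[keep]) - 1L
  y <- numeric(length(k))
  last <- cumsum(n_int[keep])
  y[last] <- as.numeric(death[keep])
  tibble::tibble(
    patient_id = cohort$patient_id[idx],
    strategy = cohort$strategy[idx],
    k = as.integer(k),
    Y_k = y
  )
}

# Count, per person-period row, qualifying records with
# start_day - window < record_day <= start_day, via one findInterval pass
# over patient-blocked encoded positions.
window_count <- function(row_pid, row_day, rec_pid, rec_day, window_days,
                         pid_levels) {
  if (length(rec_pid) == 0) {
    return(numeric(length(row_pid)))
  }
  big <- 1e7
  rec_code <- sort((match(rec_pid, pid_levels) - 1) * big + rec_day)
  code_at <- function(day) {
    findInterval((match(row_pid, pid_levels) - 1) * big + day, rec_code)
  }
  if (is.infinite(window_days)) {
    lower <- (match(row_pid, pid_levels) - 1) * big - 1
    code_at(row_day) - findInterval(lower, rec_code)
  } else {
    code_at(row_day) - code_at(row_day - window_days)
  }
}

#' Attach time-varying covariate flags
#'
#' Adds one column per time-varying covariate to the person-period table,
#' evaluated at each interval's start (baseline + k intervals): diagnosis
#' flags switch on at the first qualifying record on or before the interval
#' start and stay on; co-medication flags are 1 when a qualifying fill
#' falls inside the currency window (default 183 days) ending at the
#' interval start.
#'
#' @param person_periods From [expand_person_periods()].
#' @param cohort The cohort (for baseline dates).
#' @param diagnoses,drug_covariates Registry covariate tables.
#' @param drug_window_days Currency window for co-medication flags.
#' @param interval_days Days per interval.
#' @return `person_periods` with `tv_<name>` columns.
#' @export
attach_time_varying <- function(person_periods, cohort, diagnoses,
                                drug_covariates, drug_window_days = 183,
                                interval_days = 30.4375) {
  base <- cohort$baseline_date[match(person_periods$patient_id, cohort$patient_id)]
  start_day <- as.numeric(base) + floor(person_periods$k * interval_days)
  pid_levels <- unique(cohort$patient_id)
  out <- person_periods
  for (cond in comorbidity_names()) {
    rec <- diagnoses[diagnoses$condition == cond, , drop = FALSE]
    cnt <- window_count(
      person_periods$patient_id, start_day,
      rec$patient_id, as.numeric(rec$date), Inf, pid_levels
    )
    out[[paste0("tv_", cond)]] <- as.numeric(cnt > 0)
  }
  for (grp in drug_group_names()) {
    rec <- drug_covariates[drug_covariates$drug_group == grp, , drop = FALSE]
    cnt <- window_count(
      person_periods$patient_id, start_day,
      rec$patient_id, as.numeric(rec$date), drug_window_days, pid_levels
    )
    out[[paste0("tv_", grp)]] <- as.numeric(cnt > 0)
  }
  out
}

#' Censor person-periods at the first protocol deviation
#'
#' Produces the per-protocol person-period table: records after a patient's
#' deviation interval are dropped; the deviation interval itself is kept
#' with the censoring indicator `C_k = 1` (and `Y_k` forced to 0) so
#' censoring models can be fitted, unless the patient dies in that same
#' interval, in which case the death is counted and the record is not
#' censored. The intention-to-treat table is left untouched.
#'
#' @param person_periods From [expand_person_periods()] (optionally with
#'   time-varying columns attached).
#' @param deviations From [deviation_time()]: `patient_id`,
#'   `deviation_month`.
#' @return Per-protocol person-period table with a `C_k` column. Outcome
#'   models should use rows with `C_k == 0`; censoring models use all rows.
#' @export
censor_at_deviation <- function(person_periods, deviations) {
  if (any(deviations$deviation_month <= 0, na.rm = TRUE)) {
    stop("deviation in interval 0 is impossible: episodes start covered",
      call. = FALSE
    )
  }
  dev <- deviations$deviation_month[
    match(person_periods$patient_id, deviations$patient_id)
  ]
  dev[is.na(dev)] <- .Machine$integer.max
  keep <- person_periods$k <= dev
  out <- person_periods[keep, , drop = FALSE]
  dev_k <- dev[keep]
  at_dev <- out$k == dev_k
  out$C_k <- as.numeric(at_dev & out$Y_k == 0)
  out$Y_k[out$C_k == 1] <- 0
  out
}
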