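# Continuous-treatment episodes from dispensation streams: days of supply
# from the defined daily dose, stockpiling of unused supply, and the first
# protocol deviation (60-day gap or class switch) per patient.

#' Days of supply of a dispensation
#'
#' `pills * strength / ddd`, rounded to the nearest whole day, at least 1.
#'
#' @param dispensations Tibble with `drug`, `pills`, `strength`.
#' @param ddd DDD dictionary, see [ddd_table()].
#' @return The input with a `duration_days` column.
#' @export
#' @examples
#' dispensation_duration(
#'   tibble::tibble(drug = "letrozole", pills = 100, strength = 2.5)
#' )
dispensation_duration <- function(dispensations, ddd = ddd_table()) {
  require_columns(
    dispensations, c("drug", "pills", "strength"),
    "dispensation table"
  )
  if (any(ddd$ddd_mg <= 0)) {
    stop("defined daily dose must be positive", call. = FALSE)
  }
  i <- match(dispensations$drug, ddd$drug)
  if (anyNA(i)) {
    stop(
      "unknown drug code(s): ",
      paste(unique(dispensations$drug[is.na(i)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(dispensations$pills < 1) || any(dispensations$strength <= 0)) {
    stop("pills must be >= 1 and strength > 0", call. = FALSE)
  }
  dispensations$duration_days <- pmax(
    round(dispensations$pills * dispensations$strength / ddd$ddd_mg[i]), 1
  )
  dispensations
}

# Episode walk for one patient's date-sorted fills. `covered_until` is the
# first uncovered day; a new same-class fill extends supply from
# max(fill date, covered_until) (stockpiling). A gap deviation is confirmed
# on the grace_days-th uncovered day (covered_until + grace_days - 1); a
# fill of the other class before that day is a switch deviation.
walk_episode <- function(dates, classes, durations, followup_end, grace_days) {
  start <- dates[1]
  cls <- classes[1]
  covered <- start + durations[1]
  dev_date <- as.Date(NA)
  dev_kind <- "none"
  n <- length(dates)
  i <- 2L
  while (i <= n) {
    gap_dev <- covered + (grace_days - 1)
    if (classes[i] != cls) {
      if (dates[i] > gap_dev) {
        dev_date <- gap_dev
        dev_kind <- "gap"
      } else {
        dev_date <- dates[i]
        dev_kind <- "switch"
      }
      break
    }
    if (dates[i] - covered >= grace_days) {
      dev_date <- gap_dev
      dev_kind <- "gap"
      break
    }
    covered <- max(dates[i], covered) + durations[i]
    i <- i + 1L
  }
  if (dev_kind == "none" && !is.na(followup_end)) {
    gap_dev <- covered + (grace_days - 1)
    if (gap_dev < followup_end) {
      dev_date <- gap_dev
      dev_kind <- "gap"
    }
  }
  if (!is.na(dev_date) && !is.na(followup_end) && dev_date >= followup_end) {
    dev_date <- as.Date(NA)
    dev_kind <- "none"
  }
  list(
    drug_class = cls, start = start, covered_until = covered,
    deviation_date = dev_date, deviation_kind = dev_kind
  )
}

#' Reconstruct continuous-treatment episodes
#'
#' Treatment is considered continuous while the gap between the end of
#' supply and the next same-class fill stays below `grace_days` (default 60
#' days); unused supply carries forward. The first deviation per patient is
#' either a confirmed gap (dated the `grace_days`-th day without supply) or
#' a fill of the other drug class (dated at that fill). A patient whose
#' supply plus grace period extends to the end of follow-up never deviates.
#'
#' @param dispensations Endocrine dispensation table (`patient_id`, `drug`,
#'   `date`, `pills`, `strength`).
#' @param followup_end Either a Date vector-free tibble with `patient_id`
#'   and `followup_end_date` (e.g. the cohort) or `NULL`, in which case
#'   open-ended follow-up is assumed and only switch/gap-between-fills
#'   deviations are detected.
#' @param grace_days Allowed gap, in days, before declaring discontinuation.
#' @return One row per patient: `patient_id`, `drug_class`, `start`,
#'   `covered_until` (first day without supply), `deviation_date`,
#'   `deviation_kind` (`"gap"`, `"switch"` or `"none"`).
#' @export
build_episodes <- function(dispensations, followup_end = NULL, grace_days = 60) {
  disp <- dispensation_duration(dispensations)
  disp <- disp[disp$drug %in% endocrine_drugs(), , drop = FALSE]
  if (nrow(disp) == 0) {
    stop("no endocrine dispensations: episodes need at least one fill",
      call. = FALSE
    )
  }
  disp$drug_class <- drug_class_of(disp$drug)
  disp <- dplyr::arrange(disp, .data$patient_id, .data$date)

  fu <- NULL
  if (!is.null(followup_end)) {
    require_columns(
      followup_end, c("patient_id", "followup_end_date"),
      "followup_end"
    )
    fu <- setNames(followup_end$followup_end_date, followup_end$patient_id)
  }

  split_idx <- split(seq_len(nrow(disp)), disp$patient_id)
  pids <- names(split_idx)
  eps <- lapply(pids, function(pid) {
    i <- split_idx[[pid]]
    end <- if (!is.null(fu) && pid %in% names(fu)) fu[[pid]] else as.Date(NA)
    walk_episode(
      disp$date[i], disp$drug_class[i], disp$duration_days[i],
      end, grace_days
    )
  })
  origin <- as.Date("1970-01-01")
  tibble::tibble(
    patient_id = pids,
    drug_class = vapply(eps, `[[`, character(1), "drug_class"),
    start = as.Date(vapply(eps, function(e) as.numeric(e$start), 0), origin = origin),
    covered_until = as.Date(
      vapply(eps, function(e) as.numeric(e$covered_until), 0),
      origin = origin
    ),
    deviation_date = as.Date(
      vapply(eps, function(e) as.numeric(e$deviation_date), 0),
      origin = origin
    ),
    deviation_kind = vapply(eps, `[[`, character(1), "deviation_kind")
  )
}

#' Interval index of the protocol deviation
#'
#' Maps each episode's deviation date to the 0-based discrete follow-up
#' interval containing it (months since baseline), for per-protocol
#' censoring. Adherent patients get `NA`.
#'
#' @param episodes Output of [build_episodes()].
#' @param baseline Tibble with `patient_id` and `baseline_date`.
#' @param interval_days Days per interval.
#' @return Tibble `patient_id`, `deviation_month` (integer or `NA`).
#' @export
deviation_time <- function(episodes, baseline, interval_days = 30.4375) {
  require_columns(baseline, c("patient_id", "baseline_date"), "baseline")
  ep <- dplyr::inner_join(
    episodes, baseline[c("patient_id", "baseline_date")],
    by = "patient_id"
  )
  days <- as.numeric(ep$deviation_date - ep$baseline_date)
  if (any(days <= 0, na.rm = TRUE)) {
    stop("deviation on or before baseline: inconsistent episode data",
      call. = FALSE
    )
  }
  tibble::tibble(
    patient_id = ep$patient_id,
    deviation_month = as.integer(floor(days / interval_days))
  )
}
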