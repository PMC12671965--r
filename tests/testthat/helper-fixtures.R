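# Hand-built fixtures and independent oracles shared across test files.

# Minimal patient row; override fields as needed.
fixture_patient <- function(patient_id = "P1",
                            age = 68,
                            diagnosis_date = as.Date("2011-01-01"),
                            surgery_date = as.Date("2011-01-20"),
                            ...) {
  base <- tibble::tibble(
    patient_id = patient_id,
    sex = "female",
    age = age,
    diagnosis_date = diagnosis_date,
    surgery_date = surgery_date,
    clear_margins = TRUE,
    hr_positive = TRUE,
    postmenopausal = TRUE,
    prior_malignancy = FALSE,
    bilateral = FALSE,
    stage = "1", t_class = "T1", n_class = "N0",
    grade = "2", her2 = "negative", side = "right",
    chemotherapy = 0, radiotherapy = 0, antibody = 0,
    marital = "married_cohabiting", education = "high_school",
    employment = "employed",
    death_date = as.Date(NA), emigration_date = as.Date(NA)
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

fixture_fill <- function(patient_id, drug, date, pills = 100,
                         strength = NULL) {
  dict <- ddd_table()
  if (is.null(strength)) strength <- dict$strength_mg[match(drug, dict$drug)]
  tibble::tibble(
    patient_id = patient_id, drug = drug, date = as.Date(date),
    pills = pills, strength = strength
  )
}

empty_diagnoses <- function() {
  tibble::tibble(
    patient_id = character(), condition = character(),
    date = as.Date(character())
  )
}

empty_drug_covariates <- function() {
  tibble::tibble(
    patient_id = character(), drug_group = character(),
    date = as.Date(character())
  )
}

# Brute-force day-by-day supply simulator: the independent oracle for the
# episode engine. Walks calendar days, stockpiles supply from each fill,
# and reports the first deviation (60 consecutive uncovered days, or a
# fill of the other class while not yet gap-deviated).
brute_force_episode <- function(fills, followup_end, grace_days = 60) {
  fills <- dispensation_duration(fills)
  fills$drug_class <- c(
    letrozole = "aromatase_inhibitor", anastrozole = "aromatase_inhibitor",
    exemestane = "aromatase_inhibitor", tamoxifen = "tamoxifen"
  )[fills$drug]
  fills <- fills[order(fills$date), ]
  cls <- fills$drug_class[1]
  start <- fills$date[1]
  horizon <- max(followup_end, max(fills$date) + 2000)
  days <- as.integer(seq(start, horizon, by = 1) - start)
  supply_end <- -1 # last covered day offset
  uncovered_run <- 0
  dev_date <- as.Date(NA)
  dev_kind <- "none"
  fi <- 1
  for (d in days) {
    today <- start + d
    if (today >= followup_end) break # deviations count only within follow-up
    # process fills due today
    while (fi <= nrow(fills) && fills$date[fi] == today) {
      if (fills$drug_class[fi] != cls) {
        dev_date <- today
        dev_kind <- "switch"
        break
      }
      from <- max(d, supply_end + 1)
      supply_end <- from + fills$duration_days[fi] - 1
      fi <- fi + 1
    }
    if (dev_kind != "none") break
    if (d <= supply_end) {
      uncovered_run <- 0
    } else {
      uncovered_run <- uncovered_run + 1
      if (uncovered_run >= grace_days) {
        dev_date <- today
        dev_kind <- "gap"
        break
      }
    }
  }
  if (!is.na(dev_date) && dev_date >= followup_end) {
    dev_date <- as.Date(NA)
    dev_kind <- "none"
  }
  list(deviation_date = dev_date, deviation_kind = dev_kind)
}

# Random fill stream for property tests: mixed prompt/late refills,
# occasional switches, random supply sizes.
random_fill_stream <- function(patient_id, start_date = as.Date("2010-03-01")) {
  drugs_ai <- c("letrozole", "anastrozole", "exemestane")
  cls <- sample(c("ai", "tam"), 1)
  drug <- if (cls == "ai") sample(drugs_ai, 1) else "tamoxifen"
  n_fills <- sample(1:10, 1)
  date <- start_date
  rows <- list()
  for (i in seq_len(n_fills)) {
    pills <- sample(c(28, 30, 90, 98, 100), 1)
    rows[[i]] <- fixture_fill(patient_id, drug, date, pills = pills)
    dur <- dispensation_duration(rows[[i]])$duration_days
    gap <- sample(c(0, 0, 0, sample(1:120, 1)), 1)
    date <- date + dur + gap
    if (runif(1) < 0.15) {
      cls <- setdiff(c("ai", "tam"), cls)
      drug <- if (cls == "ai") sample(drugs_ai, 1) else "tamoxifen"
    }
  }
  dplyr::bind_rows(rows)
}
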