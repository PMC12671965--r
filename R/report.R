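# Report rendering: effect-measure tables (risks and risk differences to
# 1 decimal place, ratios to 2), risk-curve files, and the exclusion-ledger
# flowchart counts; plus delimited-text registry IO.

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt2 <- function(x) formatC(x, format = "f", digits = 2)

fmt_cell <- function(est, lower = NA, upper = NA, fmt = fmt1) {
  if (is.na(est)) {
    return(NA_character_)
  }
  if (is.na(lower) || is.na(upper)) {
    return(fmt(est))
  }
  sprintf("%s [%s-%s]", fmt(est), fmt(lower), fmt(upper))
}

#' Render a percentage cell
#'
#' Display helper matching the reporting convention for baseline tables:
#' `n (percent)` with the percentage to 1 decimal place.
#'
#' @param n Count in the cell.
#' @param total Column total.
#' @return Character, e.g. `"2437 (30.3)"`.
#' @export
render_pct_cell <- function(n, total) {
  sprintf("%d (%s)", n, fmt1(100 * n / total))
}

boot_ci_of <- function(x, measure) {
  if (!inherits(x, "emul_boot")) {
    return(c(NA_real_, NA_real_))
  }
  row <- x$ci[x$ci$measure == measure, ]
  c(row$lower, row$upper)
}

effects_of <- function(x) {
  if (inherits(x, "emul_boot")) {
    return(x$point$effects)
  }
  if (inherits(x, "emul_analysis")) {
    return(x$effects)
  }
  if (inherits(x, "emul_effects")) {
    return(x)
  }
  stop("cannot extract effect estimates from object of class ",
    paste(class(x), collapse = "/"),
    call. = FALSE
  )
}

#' Render the effect-measure table
#'
#' Builds the results table of an emulation report: one row per analysis
#' with 5-year risks per strategy, risk difference, risk ratio and average
#' hazard ratio, with percentile bootstrap intervals when available. Risks
#' and risk differences are shown to 1 decimal place (percent scale),
#' ratios to 2.
#'
#' @param results Named list of [run_analysis()] / [bootstrap_cis()] /
#'   [effect_measures()] objects (names become the `analysis` column).
#' @return A tibble with character cells ready for export.
#' @export
#' @examples
#' curve <- function(r) tibble::tibble(
#'   strategy = "s", month = 1:60,
#'   hazard = 0, risk = r
#' )
#' eff <- effect_measures(curve(0.166), curve(0.105))
#' render_effects_table(list("opioid users" = eff))
render_effects_table <- function(results) {
  if (length(results) == 0) {
    return(tibble::tibble(
      analysis = character(), risk_ai = character(),
      risk_tam = character(), rd = character(), rr = character(),
      hr = character()
    ))
  }
  if (is.null(names(results))) names(results) <- paste("analysis", seq_along(results))
  purrr::imap_dfr(results, function(x, nm) {
    ef <- effects_of(x)
    ci_rai <- 100 * boot_ci_of(x, "risk_ai_5y")
    ci_rtam <- 100 * boot_ci_of(x, "risk_tam_5y")
    ci_rd <- boot_ci_of(x, "rd")
    ci_rr <- boot_ci_of(x, "rr")
    ci_hr <- boot_ci_of(x, "avg_hr")
    tibble::tibble(
      analysis = nm,
      risk_ai = fmt_cell(100 * ef$risk_ai_5y, ci_rai[1], ci_rai[2]),
      risk_tam = fmt_cell(100 * ef$risk_tam_5y, ci_rtam[1], ci_rtam[2]),
      rd = fmt_cell(ef$rd, ci_rd[1], ci_rd[2]),
      rr = fmt_cell(ef$rr, ci_rr[1], ci_rr[2], fmt2),
      hr = fmt_cell(ef$avg_hr, ci_hr[1], ci_hr[2], fmt2)
    )
  })
}

#' Write report files for a set of analyses
#'
#' Emits the effect-measure table, per-analysis standardized risk curves
#' (for cumulative-incidence plots) and the exclusion-ledger flowchart
#' counts as tab-separated text files.
#'
#' @param results Named list of analysis results (see
#'   [render_effects_table()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  eff_path <- file.path(dir, "effect_estimates.tsv")
  readr::write_tsv(render_effects_table(results), eff_path)
  paths <- c(paths, eff_path)

  curves <- purrr::imap_dfr(results, function(x, nm) {
    obj <- if (inherits(x, "emul_boot")) x$point else x
    if (inherits(obj, "emul_analysis")) {
      dplyr::mutate(obj$curves, analysis = nm, .before = 1)
    } else {
      NULL
    }
  })
  if (nrow(curves) > 0) {
    curve_path <- file.path(dir, "risk_curves.tsv")
    readr::write_tsv(curves, curve_path)
    paths <- c(paths, curve_path)
  }

  ledgers <- purrr::imap_dfr(results, function(x, nm) {
    obj <- if (inherits(x, "emul_boot")) x$point else x
    if (inherits(obj, "emul_analysis") && !is.null(obj$ledger)) {
      dplyr::mutate(obj$ledger, analysis = nm, .before = 1)
    } else {
      NULL
    }
  })
  if (nrow(ledgers) > 0) {
    ledger_path <- file.path(dir, "exclusion_ledger.tsv")
    readr::write_tsv(ledgers, ledger_path)
    paths <- c(paths, ledger_path)
  }
  invisible(paths)
}

#' Write or read registry tables as delimited text
#'
#' Four tab-separated files (`patients.tsv`, `dispensations.tsv`,
#' `diagnoses.tsv`, `drug_covariates.tsv`) with ISO-8601 dates and one
#' header row. Generator-internal dot-prefixed columns are dropped on
#' write.
#'
#' @param registry Registry list (see [simulate_registry()]).
#' @param dir Directory.
#' @return `write_registry()` returns the paths invisibly;
#'   `read_registry()` returns the registry list.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("patients", "dispensations", "diagnoses", "drug_covariates")
  paths <- file.path(dir, paste0(nm, ".tsv"))
  for (i in seq_along(nm)) {
    tbl <- registry[[nm[i]]]
    tbl <- tbl[!startsWith(names(tbl), ".")]
    readr::write_tsv(tbl, paths[i])
  }
  invisible(paths)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  rd <- function(f, types) {
    readr::read_tsv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  list(
    patients = rd("patients.tsv", readr::cols(
      patient_id = "c", sex = "c", stage = "c", t_class = "c", n_class = "c",
      grade = "c", her2 = "c", side = "c", marital = "c", education = "c",
      employment = "c", vital_status = "c",
      diagnosis_date = readr::col_date(), surgery_date = readr::col_date(),
      death_date = readr::col_date(), emigration_date = readr::col_date(),
      .default = readr::col_guess()
    )),
    dispensations = rd("dispensations.tsv", readr::cols(
      patient_id = "c", drug = "c", date = readr::col_date(),
      pills = "d", strength = "d"
    )),
    diagnoses = rd("diagnoses.tsv", readr::cols(
      patient_id = "c", condition = "c", date = readr::col_date()
    )),
    drug_covariates = rd("drug_covariates.tsv", readr::cols(
      patient_id = "c", drug_group = "c", date = readr::col_date()
    ))
  )
}
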