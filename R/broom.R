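# broom-style tidiers.

#' Tidy a pooled logistic fit
#'
#' @param x An `emul_pooled_logistic`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`.
#' @method tidy emul_pooled_logistic
#' @export
tidy.emul_pooled_logistic <- function(x, exponentiate = FALSE, ...) {
  if (x$time_form == "saturated") {
    return(tibble::tibble(
      term = sprintf("hazard[a=%d,k=%d]", x$cells$a, x$cells$k),
      estimate = x$cells$hazard
    ))
  }
  est <- x$coefficients
  if (exponentiate) est <- exp(est)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @rdname tidy.emul_pooled_logistic
#' @method glance emul_pooled_logistic
#' @export
glance.emul_pooled_logistic <- function(x, ...) {
  tibble::tibble(
    n_person_periods = x$n_rows,
    n_events = x$n_events,
    time_form = x$time_form,
    converged = x$converged %||% TRUE
  )
}

#' Tidy effect estimates
#'
#' One row per effect measure; for bootstrap results, percentile
#' confidence limits are attached.
#'
#' @param x An `emul_effects`, `emul_analysis` or `emul_boot`.
#' @param ... Unused.
#' @return A tibble with `measure`, `estimate` (+ `conf.low`, `conf.high`).
#' @method tidy emul_effects
#' @export
tidy.emul_effects <- function(x, ...) {
  v <- effects_vector(x)
  tibble::tibble(measure = names(v), estimate = unname(v))
}

#' @rdname tidy.emul_effects
#' @method tidy emul_analysis
#' @export
tidy.emul_analysis <- function(x, ...) tidy.emul_effects(x$effects)

#' @rdname tidy.emul_effects
#' @method tidy emul_boot
#' @export
tidy.emul_boot <- function(x, ...) {
  dplyr::left_join(
    tidy.emul_effects(x$point$effects),
    dplyr::rename(x$ci, conf.low = "lower", conf.high = "upper"),
    by = "measure"
  )
}

#' @rdname tidy.emul_effects
#' @method glance emul_analysis
#' @export
glance.emul_analysis <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$cohort),
    n_ai = sum(x$cohort$strategy == "aromatase_inhibitor"),
    n_tam = sum(x$cohort$strategy == "tamoxifen"),
    n_events = sum(x$person_periods$Y_k),
    contrast = x$config$contrast,
    adjustment = x$config$adjustment
  )
}
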