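# Weighted pooled logistic outcome model on person-period records, with
# restricted-cubic-spline time and a strategy-by-time product term;
# standardized cumulative incidence and 5-year effect measures.

#' Fit the pooled logistic hazard model
#'
#' Weighted maximum-likelihood logistic regression of death-in-interval on
#' the assigned strategy, a restricted cubic spline of follow-up time, and
#' (optionally) their product term. For the covariate-adjusted sensitivity
#' variant, baseline covariate main effects are included instead of IP
#' weights and risks are later standardized over the empirical covariate
#' distribution (g-formula). With `time_form = "saturated"` the model has
#' one hazard parameter per strategy-interval cell (fitted in closed form
#' as weighted event proportions), which makes the standardized risk curve
#' coincide with the weighted Kaplan-Meier estimate.
#'
#' @param person_periods Person-period table (rows with `C_k = 1`, if
#'   present, are excluded from the fit).
#' @param weights Weight tibble from [combine_weights()] / [fit_iptw()], or
#'   `NULL` for an unweighted fit.
#' @param include_interaction Include the strategy-by-time product term.
#' @param covariates Optional baseline covariate names to adjust for in the
#'   model (requires `cohort`).
#' @param cohort Cohort tibble; required when `covariates` is given (also
#'   used as the standardization population).
#' @param spline Time spline, see [spline_spec()].
#' @param time_form `"spline"` or `"saturated"`.
#' @return An object of class `emul_pooled_logistic`.
#' @export
fit_pooled_logistic <- function(person_periods, weights = NULL,
                                include_interaction = TRUE,
                                covariates = NULL, cohort = NULL,
                                spline = spline_spec(),
                                time_form = c("spline", "saturated")) {
  time_form <- match.arg(time_form)
  pp <- person_periods
  if ("C_k" %in% names(pp)) pp <- pp[pp$C_k == 0, , drop = FALSE]
  a <- as.numeric(pp$strategy == "aromatase_inhibitor")
  if (length(unique(pp$strategy[pp$Y_k == 1])) < 2 && time_form == "spline") {
    stop(
      "no events in at least one arm: the hazard contrast is not ",
      "estimable; enlarge the data or pool arms",
      call. = FALSE
    )
  }

  w <- rep(1, nrow(pp))
  if (!is.null(weights)) {
    if ("k" %in% names(weights)) {
      key <- paste(pp$patient_id, pp$k)
      w <- weights$w_total[match(key, paste(weights$patient_id, weights$k))]
    } else {
      w <- (weights[["w_total"]] %||% weights[["w_treatment"]])[
        match(pp$patient_id, weights$patient_id)
      ]
    }
    if (anyNA(w)) stop("weights do not cover all person-periods", call. = FALSE)
  }

  if (time_form == "saturated") {
    cells <- dplyr::tibble(a = a, k = pp$k, y = pp$Y_k, w = w) |>
      dplyr::group_by(.data$a, .data$k) |>
      dplyr::summarise(
        hazard = sum(.data$w * .data$y) / sum(.data$w),
        at_risk = sum(.data$w),
        .groups = "drop"
      )
    return(structure(
      list(
        time_form = "saturated", cells = cells, spline = spline,
        include_interaction = TRUE, covariates = NULL,
        n_rows = nrow(pp), n_events = sum(pp$Y_k),
        max_k = max(pp$k)
      ),
      class = "emul_pooled_logistic"
    ))
  }

  y <- pp$Y_k
  ks <- pp$k
  if (is.null(covariates)) {
    # the design depends on rows only through (strategy, interval):
    # collapse to weighted event/at-risk cell totals before fitting
    cell <- a * (max(ks) + 1L) + ks
    wsum <- vapply(split(w, cell), sum, numeric(1))
    ysum <- vapply(split(w * y, cell), sum, numeric(1))
    first <- !duplicated(cell)
    a <- a[first][order(cell[first])]
    ks <- ks[first][order(cell[first])]
    y <- ifelse(wsum > 0, ysum / wsum, 0)
    w_fit <- unname(wsum)
  } else {
    w_fit <- w
  }
  S <- rcs_basis(ks, spline)
  X <- cbind("(Intercept)" = 1, ai = a, S)
  if (include_interaction) {
    XI <- S * a
    colnames(XI) <- paste0("ai:", colnames(S))
    X <- cbind(X, XI)
  }
  Xcov <- NULL
  if (!is.null(covariates)) {
    if (is.null(cohort)) {
      stop("covariate adjustment needs the cohort table", call. = FALSE)
    }
    Xcov_all <- cohort_design(cohort, covariates)
    Xcov_all <- Xcov_all[, colnames(Xcov_all) != "(Intercept)", drop = FALSE]
    Xcov <- Xcov_all[match(pp$patient_id, cohort$patient_id), , drop = FALSE]
    X <- cbind(X, Xcov)
  }
  fit <- fit_logistic(X, y, w_fit)
  if (any(!is.finite(fit$coefficients))) {
    stop("pooled logistic fit produced non-finite coefficients", call. = FALSE)
  }
  structure(
    list(
      time_form = "spline",
      coefficients = fit$coefficients,
      converged = fit$converged,
      spline = spline,
      include_interaction = include_interaction,
      covariates = covariates,
      std_design = if (!is.null(covariates)) {
        Xcov_all <- cohort_design(cohort, covariates)
        Xcov_all[, colnames(Xcov_all) != "(Intercept)", drop = FALSE]
      },
      n_rows = nrow(pp),
      n_events = sum(pp$Y_k),
      max_k = max(pp$k)
    ),
    class = "emul_pooled_logistic"
  )
}

#' @export
print.emul_pooled_logistic <- function(x, ...) {
  cat("<emul_pooled_logistic> (", x$time_form, " time), ",
    x$n_rows, " person-periods, ", x$n_events, " events\n",
    sep = ""
  )
  if (x$time_form == "spline") print(round(x$coefficients, 4))
  invisible(x)
}

# Interval hazards under a given strategy for a spline-time fit: either the
# marginal hazard (weighted population) or an n_patients x K matrix of
# conditional hazards for g-formula standardization.
predict_hazard <- function(fit, strategy, ks) {
  a <- as.numeric(strategy == "aromatase_inhibitor")
  S <- rcs_basis(ks, fit$spline)
  X <- cbind("(Intercept)" = 1, ai = a, S)
  if (fit$include_interaction) {
    XI <- S * a
    colnames(XI) <- paste0("ai:", colnames(S))
    X <- cbind(X, XI)
  }
  beta <- fit$coefficients
  if (is.null(fit$covariates)) {
    drop(plogis(X %*% beta[colnames(X)]))
  } else {
    eta_t <- drop(X %*% beta[colnames(X)])
    eta_c <- drop(fit$std_design %*% beta[colnames(fit$std_design)])
    outer(eta_c, eta_t, function(c, t) plogis(c + t))
  }
}

#' Standardized cumulative incidence curve
#'
#' Predicted interval hazards under the given strategy, accumulated by the
#' product-limit identity R(t) = 1 - prod(1 - h_k). For IP-weighted fits
#' the prediction is marginal in the weighted pseudo-population; for
#' covariate-adjusted fits, per-patient survival curves are averaged over
#' the empirical covariate distribution of the cohort (g-formula).
#'
#' @param fit From [fit_pooled_logistic()].
#' @param strategy `"aromatase_inhibitor"` or `"tamoxifen"`.
#' @param max_months Months of follow-up to predict.
#' @return Tibble of class `emul_risk_curve`: `strategy`, `month` (1-based,
#'   risk at the end of the month), `hazard`, `risk`.
#' @export
standardized_risk_curve <- function(fit, strategy, max_months = 60L) {
  ks <- seq_len(max_months) - 1L
  if (fit$time_form == "saturated") {
    a <- as.numeric(strategy == "aromatase_inhibitor")
    cells <- fit$cells[fit$cells$a == a, , drop = FALSE]
    h <- rep(0, max_months)
    h[cells$k + 1L] <- cells$hazard
    h <- h[seq_len(max_months)]
  } else if (is.null(fit$covariates)) {
    h <- predict_hazard(fit, strategy, ks)
  } else {
    H <- predict_hazard(fit, strategy, ks) # patients x K conditional hazards
    surv <- apply(1 - H, 1, cumprod) # K x patients
    risk <- 1 - rowMeans(surv)
    marg_surv <- c(1, rowMeans(surv))
    h <- 1 - marg_surv[-1] / marg_surv[-length(marg_surv)]
    out <- tibble::tibble(
      strategy = strategy, month = seq_len(max_months),
      hazard = h, risk = risk
    )
    class(out) <- c("emul_risk_curve", class(out))
    return(out)
  }
  out <- tibble::tibble(
    strategy = strategy,
    month = seq_len(max_months),
    hazard = h,
    risk = 1 - cumprod(1 - h)
  )
  class(out) <- c("emul_risk_curve", class(out))
  out
}

#' 5-year effect measures from a pair of risk curves
#'
#' Risk difference (percentage points) and risk ratio at the horizon from
#' the two standardized curves, and the average hazard ratio by 5 years
#' (the exponentiated strategy coefficient of the no-interaction pooled
#' logistic model).
#'
#' @param curve_ai,curve_tam Risk curves from [standardized_risk_curve()].
#' @param fit_no_interaction Optional no-interaction fit for the average
#'   hazard ratio.
#' @param horizon_months Horizon (both curves must reach it).
#' @return An object of class `emul_effects`: a list with `risk_ai_5y`,
#'   `risk_tam_5y` (probabilities), `rd` (percentage points), `rr`,
#'   `avg_hr`.
#' @export
#' @examples
#' h <- tibble::tibble(
#'   strategy = "x", month = 1:60,
#'   hazard = 0.002, risk = 1 - (1 - 0.002)^(1:60)
#' )
#' effect_measures(h, dplyr::mutate(h, risk = risk / 2))
effect_measures <- function(curve_ai, curve_tam, fit_no_interaction = NULL,
                            horizon_months = 60L) {
  pick <- function(curve) {
    if (!horizon_months %in% curve$month) {
      stop("risk curve does not reach the ", horizon_months, "-month horizon",
        call. = FALSE
      )
    }
    curve$risk[curve$month == horizon_months]
  }
  r1 <- pick(curve_ai)
  r0 <- pick(curve_tam)
  rr <- if (r0 > 0) r1 / r0 else {
    warning("tamoxifen risk is 0: risk ratio undefined", call. = FALSE)
    NA_real_
  }
  avg_hr <- NA_real_
  if (!is.null(fit_no_interaction)) {
    if (isTRUE(fit_no_interaction$include_interaction)) {
      stop("average HR requires the model without the product term",
        call. = FALSE
      )
    }
    avg_hr <- exp(unname(fit_no_interaction$coefficients["ai"]))
  }
  structure(
    list(
      risk_ai_5y = r1,
      risk_tam_5y = r0,
      rd = 100 * (r1 - r0),
      rr = rr,
      avg_hr = avg_hr,
      horizon_months = horizon_months
    ),
    class = "emul_effects"
  )
}

#' @export
print.emul_effects <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<emul_effects> at %d months\n",
      "  risk (aromatase inhibitor): %5.1f%%\n",
      "  risk (tamoxifen):           %5.1f%%\n",
      "  risk difference:            %+5.1f percentage points\n",
      "  risk ratio:                 %5.2f\n",
      "  average hazard ratio:       %5.2f\n"
    ),
    x$horizon_months, 100 * x$risk_ai_5y, 100 * x$risk_tam_5y,
    x$rd, x$rr, x$avg_hr
  ))
  invisible(x)
}
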