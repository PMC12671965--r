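# Inverse-probability weighting: baseline treatment weights from a
# logistic model of strategy on the baseline covariates, time-varying
# censoring weights from per-arm pooled logistic models of remaining
# uncensored, and their elementwise combination.

cohort_design <- function(cohort, covariates) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop(
      "covariate(s) not found in cohort: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(covariates) == 0) {
    return(matrix(1,
      nrow = nrow(cohort),
      dimnames = list(NULL, "(Intercept)")
    ))
  }
  df <- as.data.frame(cohort[covariates])
  df <- droplevels(df)
  model.matrix(~., df)
}

#' Inverse probability of treatment weights
#'
#' Fits a main-effects logistic model of the assigned strategy on the
#' baseline covariates and weights each patient by the reciprocal of the
#' fitted probability of the strategy actually received. Stabilized weights
#' (default) put the marginal assignment probability in the numerator, so
#' they average about 1; optional symmetric percentile truncation caps
#' extreme weights.
#'
#' @param cohort Cohort from [build_cohort()].
#' @param covariates Covariate columns for the denominator model.
#' @param stabilize Use marginal probabilities as numerator.
#' @param truncate_pct Optional lower percentile in (0, 0.5), e.g. 0.01
#'   truncates at the 1st/99th weight percentiles.
#' @return Tibble `patient_id`, `p_assigned`, `w_treatment`, `truncated`;
#'   the fitted coefficients are in attribute `"model"`.
#' @export
fit_iptw <- function(cohort, covariates = baseline_covariate_names(),
                     stabilize = TRUE, truncate_pct = NULL) {
  X <- cohort_design(cohort, covariates)
  a <- as.numeric(cohort$strategy == "aromatase_inhibitor")
  if (length(unique(a)) < 2) {
    stop("both strategies must be present to fit treatment weights",
      call. = FALSE
    )
  }
  fit <- fit_logistic(X, a)
  p1 <- fit$fitted
  eps <- 1e-12
  if (any(p1 <= eps | p1 >= 1 - eps)) {
    off <- which(p1 <= eps | p1 >= 1 - eps)
    stop(
      "non-overlap: fitted assignment probabilities of 0 or 1 for ",
      length(off), " patient(s), e.g. ",
      paste(head(cohort$patient_id[off], 5), collapse = ", "),
      call. = FALSE
    )
  }
  p_assigned <- ifelse(a == 1, p1, 1 - p1)
  num <- if (stabilize) ifelse(a == 1, mean(a), 1 - mean(a)) else 1
  w <- num / p_assigned
  truncated <- rep(FALSE, length(w))
  if (!is.null(truncate_pct)) {
    stopifnot(truncate_pct > 0, truncate_pct < 0.5)
    lims <- quantile(w, c(truncate_pct, 1 - truncate_pct))
    truncated <- w < lims[1] | w > lims[2]
    w <- pmin(pmax(w, lims[1]), lims[2])
  }
  out <- tibble::tibble(
    patient_id = cohort$patient_id,
    p_assigned = p_assigned,
    w_treatment = w,
    truncated = truncated
  )
  attr(out, "model") <- fit$coefficients
  out
}

#' Inverse probability of censoring weights
#'
#' For the per-protocol analysis: per arm, a pooled logistic model of
#' remaining uncensored (1 - C_k) on the baseline covariates, the
#' time-varying covariate flags, and a restricted cubic spline of interval
#' index, fitted on intervals at risk of deviation-censoring (k >= 1, since
#' every episode starts covered). The weight attached to interval k is the
#' cumulative product of inverse fitted probabilities up to and including
#' k; interval 0 has weight 1.
#'
#' @param pp_periods Per-protocol person-period table from
#'   [censor_at_deviation()], with time-varying columns attached.
#' @param cohort The cohort (baseline covariates).
#' @param covariates Baseline covariates in the censoring model.
#' @param tv_covariates Time-varying covariate names (without the `tv_`
#'   prefix).
#' @param spline Time spline, see [spline_spec()].
#' @return Tibble `patient_id`, `k`, `w_censor`; per-arm model coefficients
#'   in attribute `"models"`.
#' @export
fit_ipcw <- function(pp_periods, cohort,
                     covariates = baseline_covariate_names(),
                     tv_covariates = time_varying_covariate_names(),
                     spline = spline_spec()) {
  require_columns(pp_periods, c("patient_id", "k", "C_k"), "person-period table")
  tv_cols <- paste0("tv_", tv_covariates)
  tv_cols <- intersect(tv_cols, names(pp_periods))
  ord <- order(pp_periods$patient_id, pp_periods$k)
  pp <- pp_periods[ord, , drop = FALSE]

  ci <- match(pp$patient_id, cohort$patient_id)
  Xb <- cohort_design(cohort, covariates)[ci, , drop = FALSE]
  Xt <- as.matrix(pp[tv_cols])
  S <- rcs_basis(pp$k, spline)
  X <- cbind(Xb, Xt, S)

  arm <- cohort$strategy[ci]
  p_unc <- rep(1, nrow(pp))
  models <- list()
  for (a in unique(arm)) {
    rows <- which(arm == a & pp$k >= 1L)
    if (length(rows) == 0) next
    y <- 1 - pp$C_k[rows]
    if (all(y == 1)) {
      models[[a]] <- NULL # nobody deviates in this arm: weights stay 1
      next
    }
    Xa <- X[rows, , drop = FALSE]
    keep <- colnames(Xa) == "(Intercept)" | apply(Xa, 2, function(v) var(v) > 0)
    fit <- fit_logistic(Xa[, keep, drop = FALSE], y)
    if (!fit$converged) {
      stop("censoring model did not converge (possible separation)",
        call. = FALSE
      )
    }
    models[[a]] <- fit$coefficients
    p_unc[rows] <- fit$fitted
  }

  # cumulative product of 1 / P(uncensored) within patient, ordered by k
  inv <- 1 / p_unc
  grp_change <- c(TRUE, pp$patient_id[-1] != pp$patient_id[-nrow(pp)])
  logw <- cumsum(log(inv))
  offsets <- logw - log(inv) # log cumprod up to previous row
  first_row <- which(grp_change)
  start_log <- rep(offsets[first_row], times = diff(c(first_row, nrow(pp) + 1)))
  w <- exp(logw - start_log)

  out <- tibble::tibble(
    patient_id = pp$patient_id,
    k = pp$k,
    w_censor = w
  )
  attr(out, "models") <- models
  out
}

#' Combine treatment and censoring weights
#'
#' Elementwise product aligned on patient (and interval, when censoring
#' weights are present). With `ipcw = NULL` (intention-to-treat) the total
#' weight equals the treatment weight in every interval.
#'
#' @param iptw From [fit_iptw()].
#' @param ipcw From [fit_ipcw()], or `NULL`.
#' @return Tibble `patient_id` (+ `k` when `ipcw` given), `w_treatment`,
#'   `w_censor`, `w_total`.
#' @export
combine_weights <- function(iptw, ipcw = NULL) {
  if (is.null(ipcw)) {
    return(tibble::tibble(
      patient_id = iptw$patient_id,
      w_treatment = iptw$w_treatment,
      w_censor = 1,
      w_total = iptw$w_treatment
    ))
  }
  wt <- iptw$w_treatment[match(ipcw$patient_id, iptw$patient_id)]
  if (anyNA(wt)) {
    stop("censoring weights refer to patients without treatment weights",
      call. = FALSE
    )
  }
  tibble::tibble(
    patient_id = ipcw$patient_id,
    k = ipcw$k,
    w_treatment = wt,
    w_censor = ipcw$w_censor,
    w_total = wt * ipcw$w_censor
  )
}

#' Covariate balance diagnostics
#'
#' Standardized mean differences of every expanded covariate column between
#' strategies, before and after weighting. The denominator is the
#' unweighted pooled standard deviation.
#'
#' @param cohort Cohort tibble.
#' @param weights Per-patient weights (e.g. `w_treatment` from
#'   [fit_iptw()]); `NULL` for unweighted only.
#' @param covariates Covariates to expand and compare.
#' @return Tibble `term`, `smd_unweighted`, `smd_weighted`.
#' @export
covariate_balance <- function(cohort, weights = NULL,
                              covariates = baseline_covariate_names()) {
  X <- cohort_design(cohort, covariates)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  a <- cohort$strategy == "aromatase_inhibitor"
  w <- if (is.null(weights)) {
    rep(1, nrow(cohort))
  } else {
    weights$w_treatment[match(cohort$patient_id, weights$patient_id)]
  }
  wmean <- function(x, w) sum(x * w) / sum(w)
  pooled_sd <- apply(X, 2, function(x) {
    sqrt((var(x[a]) + var(x[!a])) / 2)
  })
  smd <- function(wv) {
    d <- apply(X, 2, function(x) wmean(x[a], wv[a]) - wmean(x[!a], wv[!a]))
    ifelse(pooled_sd > 0, d / pooled_sd, 0)
  }
  tibble::tibble(
    term = colnames(X),
    smd_unweighted = smd(rep(1, nrow(X))),
    smd_weighted = smd(w)
  )
}

#' Weight distribution diagnostics
#'
#' @param weights A weight tibble (from [fit_iptw()] or
#'   [combine_weights()]).
#' @param cohort Cohort (for the strategy of each patient).
#' @return Tibble of mean, max and percentiles of the total weight by arm.
#' @export
weight_diagnostics <- function(weights, cohort) {
  w <- weights[["w_total"]] %||% weights[["w_treatment"]]
  arm <- cohort$strategy[match(weights$patient_id, cohort$patient_id)]
  tibble::tibble(strategy = arm, w = w) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$w),
      p01 = quantile(.data$w, 0.01),
      p50 = quantile(.data$w, 0.50),
      p99 = quantile(.data$w, 0.99),
      max = max(.data$w),
      .groups = "drop"
    )
}
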