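# Thin R-side wrapper around the compiled IRLS logistic solver. Used on the
# bootstrap hot path where stats::glm's model-frame machinery dominates the
# runtime; coefficient agreement with glm() is pinned down in the test suite.
fit_logistic <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  keep <- w > 0
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    w <- w[keep]
  }
  fit <- .irls_logistic(X, as.numeric(y), as.numeric(w))
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X)
  list(
    coefficients = beta,
    fitted = drop(fit$fitted),
    converged = isTRUE(fit$converged),
    keep = keep
  )
}

# Fitted probabilities on (possibly new) design rows.
predict_logistic <- function(beta, X) {
  drop(plogis(X %*% beta))
}
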