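#' Restricted cubic spline specification
#'
#' Defines the follow-up-time basis used by the pooled logistic hazard and
#' censoring models: a restricted cubic spline in the truncated-power
#' (Harrell) parameterization, constrained to be linear beyond its boundary
#' knots. The default knots sit at 6, 12, 24 and 36 months of follow-up.
#'
#' @param knots Numeric vector of at least 3 strictly increasing knot
#'   positions, in months since baseline.
#' @return An object of class `emul_spline_spec`.
#' @export
#' @examples
#' spline_spec()
#' rcs_basis(0:10, spline_spec(c(2, 5, 8)))
spline_spec <- function(knots = c(6, 12, 24, 36)) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) {
    stop("a restricted cubic spline needs at least 3 knots", call. = FALSE)
  }
  if (any(diff(knots) <= 0)) {
    stop("spline knots must be strictly increasing", call. = FALSE)
  }
  structure(list(knots = knots), class = "emul_spline_spec")
}

#' Restricted cubic spline basis
#'
#' Evaluates the truncated-power restricted cubic spline basis at `x`.
#' With K knots the basis has K - 1 columns: the first is `x` itself and the
#' remaining K - 2 are cubic terms constrained so the function is linear
#' below the first and above the last knot.
#'
#' @param x Numeric vector of evaluation points (months since baseline).
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns, named `t`, `t_rcs1`, `t_rcs2`, ...
#' @export
rcs_basis <- function(x, spec = spline_spec()) {
  if (!inherits(spec, "emul_spline_spec")) spec <- spline_spec(spec)
  k <- spec$knots
  K <- length(k)
  x <- as.numeric(x)
  norm2 <- (k[K] - k[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = K - 1)
  out[, 1] <- x
  for (j in seq_len(K - 2)) {
    out[, j + 1] <- (pos3(x - k[j]) -
      pos3(x - k[K - 1]) * (k[K] - k[j]) / (k[K] - k[K - 1]) +
      pos3(x - k[K]) * (k[K - 1] - k[j]) / (k[K] - k[K - 1])) / norm2
  }
  colnames(out) <- c("t", paste0("t_rcs", seq_len(K - 2)))
  out
}
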