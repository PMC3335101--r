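#' Lasso soft-thresholding operator
#'
#' The scalar shrinkage rule induced by an L1 penalty:
#' `sign(b) * max(|b| - lam, 0)`.  Coefficients with `|b| <= lam` are set
#' exactly to zero, which is what turns the loading update of the joint
#' latent-variable model into a feature-selection step.
#'
#' @param b Numeric vector of coefficients.
#' @param lam Single non-negative threshold.
#' @return Numeric vector of shrunken coefficients, same length as `b`.
#' @examples
#' soft_threshold(c(-1.2, 0.5, 0.9), 0.5)
#' @seealso [weighted_soft_threshold()]
#' @export
soft_threshold <- function(b, lam) {
  check_scalar_number(lam, "lam", min = 0)
  sign(b) * pmax(abs(b) - lam, 0)
}

#' Variance-weighted soft-thresholding operator
#'
#' Adaptive variant in which the shrinkage applied to a coefficient is
#' proportional to the residual variance of its feature: the effective
#' threshold is `lam * sigma2`.  Features with high residual variance —
#' i.e. noisy features the factors explain poorly — are penalized more
#' heavily, so they are removed from the model first.
#'
#' @param b Numeric vector of coefficients.
#' @param lam Single non-negative penalty multiplier.
#' @param sigma2 Positive residual variance(s), recycled along `b`.
#' @return Numeric vector of shrunken coefficients.
#' @examples
#' weighted_soft_threshold(0.9, 0.3, sigma2 = 1)  # = soft_threshold(0.9, 0.3)
#' weighted_soft_threshold(0.9, 0.3, sigma2 = 4)  # threshold 1.2 -> 0
#' @export
weighted_soft_threshold <- function(b, lam, sigma2) {
  check_scalar_number(lam, "lam", min = 0)
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    abort("`sigma2` must contain strictly positive finite values.")
  }
  sign(b) * pmax(abs(b) - lam * sigma2, 0)
}
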