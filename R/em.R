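# EM machinery for the sparse joint latent-variable model.
#
# Model, with all data types stacked into one p x n matrix X:
#   x_i = B z_i + e_i,   z_i ~ N(0, I_q),   e_i ~ N(0, Psi diagonal),
# with q = K - 1 latent factors for K clusters.

#' E-step: posterior moments of the latent factors
#'
#' Computes the Gaussian posterior of the latent factors given the stacked
#' data: `cov = (I + B' Psi^-1 B)^-1` and, per sample,
#' `mean_i = cov B' Psi^-1 x_i`.  The posterior covariance is shared across
#' samples under the homoscedastic model.
#'
#' @param B Stacked loading matrix, p x q.
#' @param psi Positive residual variances, length p (diagonal of Psi).
#' @param X Stacked data matrix, p x n (features standardized beforehand).
#' @return List with `mean` (q x n) and `cov` (q x q, symmetric positive
#'   definite).
#' @export
em_e_step <- function(B, psi, X) {
  B <- as.matrix(B)
  if (any(!is.finite(B))) abort("Non-finite loadings in E-step.")
  if (any(psi <= 0)) abort("Residual variances must be strictly positive.")
  q <- ncol(B)
  W <- B / psi
  M <- diag(q) + crossprod(B, W)
  R <- tryCatch(chol(M), error = function(e) {
    abort("E-step system is numerically singular (ill-conditioned I + B'Psi^-1 B).")
  })
  cov <- chol2inv(R)
  cov <- (cov + t(cov)) / 2
  list(mean = cov %*% crossprod(W, X), cov = cov)
}

#' M-step: penalized update of loadings and residual variances
#'
#' First forms the unpenalized least-squares update
#' `Bhat = X E[Z]' (sum_i E[z_i z_i'])^-1`, then passes every entry through
#' the (optionally variance-weighted) soft-threshold of its data type, and
#' finally updates the diagonal residual variances from the expected
#' residual sum of squares, with a positivity floor.
#'
#' The user-facing penalty `s` of each type lies in `[0, 1]` with the
#' convention that `s = 0` selects no features (null model) and `s = 1`
#' keeps all of them.  Within each type it is mapped to an absolute
#' threshold scaled by each factor column's largest unpenalized coefficient
#' (largest coefficient-to-variance ratio in weighted mode), so thresholds
#' are free of the data scale and a dominant factor cannot dictate the
#' threshold applied to weaker factors.
#'
#' @param X Stacked data matrix, p x n.
#' @param ez Posterior means from [em_e_step()], q x n.
#' @param ez_cov Posterior covariance, q x q.
#' @param type_index Character vector of length p giving each row's data type.
#' @param penalties Named numeric vector in `[0,1]`, one entry per type.
#' @param psi Current residual variances (used for the weighted threshold).
#' @param weighted Use the variance-weighted threshold? Default `TRUE`.
#' @param var_floor Lower bound for updated residual variances.
#' @return List with `B` (sparse loading matrix), `psi` (updated variances),
#'   `B_unpenalized`, and `lambda` (the absolute per-type penalty level used).
#' @export
em_m_step <- function(X, ez, ez_cov, type_index, penalties, psi,
                      weighted = TRUE, var_floor = 1e-6) {
  n <- ncol(X)
  q <- nrow(ez)
  SZZ <- n * ez_cov + tcrossprod(ez)
  XEZt <- tcrossprod(X, ez)
  Bhat <- tryCatch(
    t(solve(SZZ, t(XEZt))),
    error = function(e) {
      jitter <- 1e-8 * mean(diag(SZZ))
      inform(sprintf(
        "Second-moment matrix nearly singular; ridge-stabilized with jitter %.2e.",
        jitter))
      t(solve(SZZ + diag(jitter, q), t(XEZt)))
    }
  )
  types <- unique(type_index)
  if (is.null(names(penalties))) names(penalties) <- types
  if (any(penalties < 0 | penalties > 1)) abort("Penalties must lie in [0, 1].")
  B <- Bhat
  lambda <- setNames(numeric(length(types)), types)
  for (tp in types) {
    idx <- which(type_index == tp)
    A <- Bhat[idx, , drop = FALSE]
    s <- penalties[[tp]]
    # thresholds scale with each factor column's own largest coefficient
    # (or coefficient/variance ratio in weighted mode): a type-wide scale
    # would let a dominant factor's threshold annihilate weaker factors
    if (weighted) {
      # clamp the weighting variances from below: a few near-perfectly
      # explained features (psi at the floor) must not set the penalty
      # scale for the whole type
      pt <- psi[idx]
      half <- (length(pt) + 1L) %/% 2L
      med <- sort(pt, partial = half)[half]
      w <- pmax(pt, 0.05 * med)
      ratio <- abs(A) / w
      lam <- (1 - s) * col_maxs(ratio)
      thr <- outer(w, lam)
    } else {
      lam <- (1 - s) * col_maxs(abs(A))
      thr <- matrix(lam, length(idx), q, byrow = TRUE)
    }
    lambda[[tp]] <- max(lam)
    B[idx, ] <- sign(A) * pmax(abs(A) - thr, 0)
  }
  # E || x - B z ||^2 with the *unpenalized* update: using the thresholded
  # B here would fold the shrinkage bias into the residual variances, and
  # under the variance-weighted penalty that feedback annihilates strongly
  # loaded features (larger shrinkage -> larger psi -> larger threshold)
  psi_new <- rowMeans(X^2) - 2 * rowSums(Bhat * XEZt) / n +
    rowSums((Bhat %*% SZZ) * Bhat) / n
  psi_new <- pmax(psi_new, var_floor)
  list(B = B, psi = psi_new, B_unpenalized = Bhat, lambda = lambda)
}

# observed-data log-likelihood of the Gaussian factor model, via Woodbury
factor_model_loglik <- function(B, psi, X) {
  n <- ncol(X); p <- nrow(X); q <- ncol(B)
  W <- B / psi
  M <- diag(q) + crossprod(B, W)
  R <- chol(M)
  logdet <- sum(log(psi)) + 2 * sum(log(diag(R)))
  WX <- crossprod(W, X)                      # q x n
  tr1 <- sum(X^2 / psi) / n
  Minv_WX <- backsolve(R, forwardsolve(t(R), WX))
  tr2 <- sum(WX * Minv_WX) / n
  -n / 2 * (p * log(2 * pi) + logdet + tr1 - tr2)
}
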