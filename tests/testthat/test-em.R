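test_that("E-step recovers the prior when loadings are zero", {
  p <- 4; q <- 2; n <- 3
  es <- em_e_step(matrix(0, p, q), rep(1.5, p), matrix(rnorm(p * n), p, n))
  expect_equal(es$mean, matrix(0, q, n), ignore_attr = TRUE)
  expect_equal(es$cov, diag(q))
})

test_that("E-step matches the scalar closed form", {
  es <- em_e_step(matrix(1, 1, 1), 1, matrix(2, 1, 1))
  expect_equal(as.numeric(es$cov), 0.5)
  expect_equal(as.numeric(es$mean), 1)
})

test_that("E-step agrees with the dense Gaussian-conditional oracle to 1e-8", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      p <- 5; q <- 2; n <- 4
      B <- matrix(rnorm(p * q), p, q)
      psi <- runif(p, 0.2, 2)
      X <- matrix(rnorm(p * n), p, n)
      es <- em_e_step(B, psi, X)
      oracle <- dense_posterior_oracle(B, psi, X)
      expect_equal(es$mean, oracle$mean, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(es$cov, oracle$cov, tolerance = 1e-8, ignore_attr = TRUE)
      expect_true(all(eigen(es$cov, symmetric = TRUE)$values > 0))
    })
  }
})

test_that("M-step with penalty 1 (full model) is the exact least-squares update", {
  withr::with_seed(7, {
    p <- 8; q <- 2; n <- 12
    B <- matrix(rnorm(p * q), p, q); psi <- runif(p, 0.5, 2)
    X <- matrix(rnorm(p * n), p, n)
    es <- em_e_step(B, psi, X)
    ms <- em_m_step(X, es$mean, es$cov, rep("a", p), c(a = 1), psi)
    SZZ <- n * es$cov + tcrossprod(es$mean)
    expect_equal(ms$B, tcrossprod(X, es$mean) %*% solve(SZZ), tolerance = 1e-10)
    expect_equal(ms$B, ms$B_unpenalized)
    expect_true(all(ms$psi > 0))
  })
})

test_that("M-step with penalty 0 shrinks every loading to exactly zero", {
  withr::with_seed(8, {
    p <- 6; q <- 2; n <- 10
    B <- matrix(rnorm(p * q), p, q); psi <- runif(p, 0.5, 2)
    X <- matrix(rnorm(p * n), p, n)
    es <- em_e_step(B, psi, X)
    ms <- em_m_step(X, es$mean, es$cov, rep("a", p), c(a = 0), psi)
    expect_true(all(ms$B == 0))
  })
})

test_that("M-step sparsity pattern equals entrywise thresholding of the full update", {
  withr::with_seed(9, {
    p <- 10; q <- 2; n <- 15
    B <- matrix(rnorm(p * q), p, q); psi <- runif(p, 0.5, 2)
    X <- matrix(rnorm(p * n), p, n)
    es <- em_e_step(B, psi, X)
    full <- em_m_step(X, es$mean, es$cov, rep("a", p), c(a = 1), psi)$B
    for (s in c(0.3, 0.6)) {
      for (weighted in c(TRUE, FALSE)) {
        ms <- em_m_step(X, es$mean, es$cov, rep("a", p), c(a = s), psi,
                        weighted = weighted)
        # reconstruct the per-column thresholds from the scalar rule
        expected <- full
        for (k in seq_len(q)) {
          if (weighted) {
            w <- pmax(psi, 0.05 * median(psi))
            lam <- (1 - s) * max(abs(full[, k]) / w)
            expected[, k] <- weighted_soft_threshold(full[, k], lam, w)
          } else {
            lam <- (1 - s) * max(abs(full[, k]))
            expected[, k] <- soft_threshold(full[, k], lam)
          }
        }
        expect_equal(ms$B, expected, tolerance = 1e-12)
      }
    }
  })
})

test_that("unpenalized EM log-likelihood is non-decreasing over iterations", {
  sim <- tiny_two_cluster(seed = 11)
  fit <- omiclust(sim$dataset, K = 2, penalties = 1, seed = 1, max_iter = 100)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("selected-feature count is monotone in the sparsity level", {
  sim <- tiny_two_cluster(seed = 12)
  # one EM sweep from the shared deterministic start: the threshold operator
  # acts on the same update, so monotonicity is exact
  counts1 <- vapply(seq(0.1, 1, by = 0.1), function(s) {
    fit <- suppressWarnings(omiclust(sim$dataset, K = 2, penalties = s,
                                     seed = 1, max_iter = 1))
    sum(attr(selected_features(fit), "counts"))
  }, numeric(1))
  expect_true(all(diff(counts1) >= 0))
  # converged fits keep the trend (small wobble from path dependence aside)
  # and hit the exact endpoints: near-null at tiny s, full model at s = 1
  counts <- vapply(c(0.15, 0.5, 1), function(s) {
    fit <- suppressWarnings(omiclust(sim$dataset, K = 2, penalties = s, seed = 1))
    sum(attr(selected_features(fit), "counts"))
  }, numeric(1))
  expect_true(all(diff(counts) >= -2))
  expect_lt(counts[1], 10)
  expect_equal(counts[3], 30)
})

test_that("unpenalized isotropic single-type fit spans the principal subspace", {
  withr::with_seed(13, {
    n <- 30; p <- 12
    X <- matrix(rnorm(p * n), p, n) + tcrossprod(rnorm(p), rnorm(n)) * 0.8
    rownames(X) <- paste0("f", 1:p); colnames(X) <- paste0("s", 1:n)
    fit <- suppressWarnings(
      omiclust(omics_dataset(a = X), K = 3, penalties = 1, isotropic = TRUE,
               scale = "center", max_iter = 5000, tol = 1e-10, seed = 1))
    B <- fit$loadings$a
    Xc <- X - rowMeans(X)
    U <- svd(Xc, nu = 2)$u
    expect_lt(principal_angle(B, U), 1e-3)
  })
})

test_that("duplicated data types receive identical loadings", {
  sim <- tiny_two_cluster(seed = 14)
  X <- sim$dataset$matrices$type1
  Y <- X; rownames(Y) <- paste0("copy_", rownames(X))
  fit <- suppressWarnings(omiclust(omics_dataset(a = X, b = Y), K = 2,
                                   penalties = 0.6, seed = 1))
  expect_equal(unname(fit$loadings$a), unname(fit$loadings$b), tolerance = 1e-8)
})
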