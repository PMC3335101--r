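# Independent oracles and small fixture builders used across the suite.

# Gaussian-conditional posterior of z given x, by explicit dense inversion
# of the joint covariance: an implementation-independent check of the
# E-step's Woodbury route.
dense_posterior_oracle <- function(B, psi, X) {
  p <- nrow(B); q <- ncol(B)
  sigma_xx <- B %*% t(B) + diag(psi, p)
  sigma_zx <- t(B)
  mean <- sigma_zx %*% solve(sigma_xx, X)
  cov <- diag(q) - sigma_zx %*% solve(sigma_xx, B)
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

# adjusted Rand by brute-force enumeration of all sample pairs
brute_force_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}

# centered L2 discrepancy of a design in [0,1]^d
centered_l2_discrepancy <- function(X) {
  n <- nrow(X); d <- ncol(X)
  a <- abs(X - 0.5)
  term2 <- sum(apply(1 + 0.5 * a - 0.5 * a^2, 1, prod))
  term3 <- 0
  for (i in 1:n) for (j in 1:n) {
    term3 <- term3 + prod(1 + 0.5 * a[i, ] + 0.5 * a[j, ] - 0.5 * abs(X[i, ] - X[j, ]))
  }
  sqrt((13 / 12)^d - 2 / n * term2 + term3 / n^2)
}

# largest principal angle (radians) between the column spaces of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}

# numerical mutual information of a unit-variance bivariate normal by 2-D
# composite-Simpson quadrature of the defining double integral
quadrature_mi <- function(rho, lim = 8, n = 800) {
  stopifnot(n %% 2 == 0)
  x <- seq(-lim, lim, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  h <- x[2] - x[1]
  G <- outer(x, x, function(x, y) {
    dens <- 1 / (2 * pi * sqrt(1 - rho^2)) *
      exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2)))
    out <- dens * log(pmax(dens, 1e-300) / (stats::dnorm(x) * stats::dnorm(y)))
    out[dens < 1e-300] <- 0
    out
  })
  (h / 3)^2 * as.numeric(t(w) %*% G %*% w)
}

# small two-type dataset with a planted two-cluster structure
tiny_two_cluster <- function(seed = 1, n = 40, p = 15, delta = 3) {
  withr::with_seed(seed, {
    labels <- rep(1:2, each = n / 2)
    mats <- lapply(1:2, function(t) {
      X <- matrix(rnorm(p * n), p, n)
      X[1:3, ] <- X[1:3, ] + rep(delta * (labels - 1.5), each = 3)
      rownames(X) <- sprintf("t%d_f%02d", t, 1:p)
      colnames(X) <- sprintf("s%02d", 1:n)
      X
    })
    names(mats) <- c("type1", "type2")
    list(dataset = omics_dataset(mats), labels = labels)
  })
}
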