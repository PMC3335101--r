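test_that("Gaussian mutual information obeys its closed form and symmetry", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.8), -0.5 * log(1 - 0.64))
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(gaussian_mi(r), gaussian_mi(-r))
  expect_true(all(diff(gaussian_mi(seq(0, 0.95, by = 0.05))) > 0))
  expect_error(gaussian_mi(1), "\\|rho\\| < 1")
  expect_error(gaussian_mi(-1.2), "\\|rho\\| < 1")
})

test_that("Gaussian mutual information matches 2-D quadrature of its definition", {
  for (rho in c(-0.9, -0.5, 0.3, 0.6, 0.8)) {
    expect_lt(abs(gaussian_mi(rho) - quadrature_mi(rho)), 1e-4)
  }
})

test_that("mutual-information enrichment detects planted cross-type correlation", {
  significant <- vapply(1:10, function(r) {
    withr::with_seed(900 + r, {
      n <- 60; p <- 120
      shared <- matrix(rnorm(20 * n), 20, n)
      a <- matrix(rnorm(p * n), p, n); b <- matrix(rnorm(p * n), p, n)
      # first 20 pairs correlated at rho ~ 0.7, rest independent
      w <- sqrt(0.7 / (1 - 0.7))
      a[1:20, ] <- (a[1:20, ] + w * shared) / sqrt(1 + w^2)
      b[1:20, ] <- (b[1:20, ] + w * shared) / sqrt(1 + w^2)
      rownames(a) <- rownames(b) <- paste0("g", 1:p)
      res <- mi_enrichment(a, b, selected = paste0("g", 1:20))
      glance(res)$shift_p_value < 0.01
    })
  }, logical(1))
  expect_gte(mean(significant), 0.9)
})

test_that("independent noise pairs concentrate near zero mutual information", {
  withr::with_seed(91, {
    a <- matrix(rnorm(50 * 80), 50, 80); b <- matrix(rnorm(50 * 80), 50, 80)
    rownames(a) <- rownames(b) <- paste0("g", 1:50)
  })
  res <- mi_enrichment(a, b, selected = paste0("g", 1:10))
  expect_lt(median(res$mi), 0.05)
  expect_lt(abs(median(res$mi[res$selected]) - median(res$mi[!res$selected])), 0.05)
})

test_that("degenerate enrichment inputs are handled", {
  withr::with_seed(92, {
    a <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), NULL))
    b <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), NULL))
  })
  single <- mi_enrichment(a[1, , drop = FALSE], b[1, , drop = FALSE])
  expect_equal(nrow(single), 1)
  expect_true(is.na(glance(single)$shift_p_value))
  a2 <- rbind(a, g3 = rep(1, 3)); b2 <- rbind(b, g3 = rnorm(3))
  expect_message(res <- mi_enrichment(a2, b2), "constant")
  expect_equal(nrow(res), 2)
})

test_that("leave-one-out k-NN reproduces hand-enumerated toy results", {
  # duplicated points with consistent labels: zero error at k = 1
  x <- matrix(c(0, 0, 5, 5, 0, 0, 5, 5), ncol = 2)
  res <- knn_loocv(x, c(1, 1, 2, 2), k_range = 1)
  expect_equal(res$cv_error, 0)

  # four points on a line, labels A A B B: the middle tie goes to the
  # lower-index neighbour, so exactly one point is misclassified at k = 1
  line <- matrix(c(1, 2, 3, 4), ncol = 1)
  res <- knn_loocv(line, c(1, 1, 2, 2), k_range = 1)
  expect_equal(res$cv_error, 0.25)
  expect_equal(res$best_k, 1L)
})

test_that("k-NN error under shuffled labels approaches one minus the majority share", {
  withr::with_seed(93, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    labels <- rep(c(1L, 2L), times = c(40, 20))
    shuffled <- sample(labels)
  })
  res <- knn_loocv(x, shuffled, k_range = 45)
  expect_lt(abs(res$cv_error - 1 / 3), 0.12)
})

test_that("k-NN CV error is invariant to feature order and global scaling", {
  withr::with_seed(94, {
    x <- matrix(rnorm(30 * 6), 30, 6)
    labels <- rep(1:2, 15)
  })
  base <- knn_loocv(x, labels, k_range = c(1, 3, 5))
  perm <- knn_loocv(x[, sample(6)], labels, k_range = c(1, 3, 5))
  scaled <- knn_loocv(7.3 * x, labels, k_range = c(1, 3, 5))
  expect_equal(base$errors, perm$errors)
  expect_equal(base$errors, scaled$errors)
})

test_that("k-NN transfer follows its deterministic voting contract", {
  train <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), ncol = 2, byrow = TRUE)
  labels <- c(1L, 1L, 2L, 2L)
  expect_equal(knn_transfer(train, labels, train[3, , drop = FALSE], k = 1), 2L)
  # k = n: every query gets the global majority; ties -> lowest cluster index
  expect_equal(knn_transfer(train, labels, matrix(c(100, 100), 1), k = 4), 1L)
  expect_error(knn_transfer(train, labels, train[1, , drop = FALSE], k = 9),
               "between 1")
})

test_that("labels transfer across split halves of a strong planted signal", {
  sim <- gen_scenario1(seed = 95, delta = 3)
  X <- t(sim$dataset$matrices$type1)
  idx <- seq(1, 100, by = 2)
  pred <- knn_transfer(X[idx, ], sim$true_labels[idx], X[-idx, ], k = 5)
  expect_gte(adjusted_rand(pred, sim$true_labels[-idx]), 0.9)
})
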