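test_that("a strong planted two-cluster signal is recovered exactly", {
  sim <- gen_scenario1(seed = 21, delta = 3)
  fit <- omiclust(sim$dataset, K = 2, penalties = 0.5, scale = "center", seed = 1)
  expect_equal(adjusted_rand(fit$labels, sim$true_labels), 1)
  expect_true(fit$converged)
})

test_that("fits are deterministic given the seed", {
  sim <- tiny_two_cluster(seed = 22)
  f1 <- omiclust(sim$dataset, K = 2, penalties = 0.6, seed = 9)
  f2 <- omiclust(sim$dataset, K = 2, penalties = 0.6, seed = 9)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("argument validation rejects impossible settings", {
  sim <- tiny_two_cluster(seed = 23, n = 10)
  expect_error(omiclust(sim$dataset, K = 1), ">= 2")
  expect_error(omiclust(sim$dataset, K = 10), "smaller than the sample count")
  expect_error(omiclust(sim$dataset, K = 2, penalties = 1.5), "\\[0, 1\\]")
})

test_that("penalty 0 yields the null model with empty selection", {
  sim <- tiny_two_cluster(seed = 24)
  expect_warning(fit <- omiclust(sim$dataset, K = 2, penalties = 0, seed = 1),
                 "null model")
  sel <- selected_features(fit)
  expect_equal(nrow(sel), 0)
  expect_equal(unname(attr(sel, "counts")), c(0L, 0L))
})

test_that("selection reports exactly the rows with surviving loadings", {
  sim <- tiny_two_cluster(seed = 25)
  fit <- suppressWarnings(omiclust(sim$dataset, K = 2, penalties = 0.5, seed = 1))
  sel <- selected_features(fit, tol = 0)
  manual <- lapply(fit$loadings, function(B) which(apply(B != 0, 1, any)))
  expect_equal(sel$index[sel$type == "type1"], unname(manual$type1))
  expect_equal(sel$index[sel$type == "type2"], unname(manual$type2))
})

test_that("a well-tuned sparse fit recovers the planted features of the sparse scenario", {
  sim <- gen_scenario2(seed = 26)
  fit <- suppressWarnings(omiclust(sim$dataset, K = 2, penalties = 0.7,
                                   scale = "center", seed = 1))
  sel <- selected_features(fit)
  expect_true(all(sim$true_features$type1 %in% sel$index[sel$type == "type1"]))
  expect_true(all(sim$true_features$type2 %in% sel$index[sel$type == "type2"]))
})

test_that("cluster assignment separates well-separated point masses", {
  centers <- cbind(c(0, 0), c(10, 0), c(0, 10))
  pm <- centers[, rep(1:3, each = 8)] + matrix(rnorm(48, sd = 0.05), 2)
  labels <- assign_clusters(pm, K = 3, seed = 1)
  expect_equal(adjusted_rand(labels, rep(1:3, each = 8)), 1)
  expect_equal(labels[1], 1L)  # renumbered by first occurrence
})

test_that("one-dimensional assignment splits at the widest gap", {
  withr::with_seed(31, {
    pm <- matrix(c(runif(10, 0, 1), runif(10, 6, 7)), 1)
    labels <- assign_clusters(pm, K = 2, seed = 1)
    # exhaustive search over all n-1 ordered split points
    ord <- order(pm[1, ])
    best_split <- which.max(diff(pm[1, ord]))
    expected <- rep(2L, 20); expected[ord[seq_len(best_split)]] <- 1L
    expect_equal(adjusted_rand(labels, expected), 1)
  })
})

test_that("assignment fails when there are fewer distinct points than clusters", {
  pm <- matrix(rep(c(1, 2), each = 5), 1)
  expect_error(assign_clusters(pm, K = 3, seed = 1), "distinct sample points")
})

test_that("prediction on the training samples reproduces the fitted labels", {
  sim <- tiny_two_cluster(seed = 27)
  fit <- omiclust(sim$dataset, K = 2, penalties = 0.6, seed = 1)
  pred <- predict(fit, sim$dataset)
  expect_equal(pred$cluster, unname(fit$labels))
  expect_named(pred, c("sample_id", "cluster", "factor_1"))
})

test_that("tidy, glance and assignments expose the fit as tables", {
  sim <- tiny_two_cluster(seed = 28)
  fit <- omiclust(sim$dataset, K = 2, penalties = 0.6, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("type", "feature", "factor", "loading"))
  expect_equal(nrow(td), 30)
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_true(gl$converged)
  ca <- cluster_assignments(fit)
  expect_equal(nrow(ca), 40)
  expect_s3_class(autoplot(fit), "ggplot")
})
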