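#!/usr/bin/env Rscript
# One-off calibration of the simulation generators' planted effect sizes.
#
# The two-cluster generators are anchored to the per-type K-means baseline:
# delta is chosen so that the baseline's cross-validated error rate lands
# near its published benchmark value (0.08 for the moderately sparse
# scenario, 0.11 for the extremely sparse one).  The resulting deltas are
# FROZEN in `default_effect_sizes` inside the package; every benchmark and
# acceptance run uses the frozen values.  The three-cluster delta is chosen
# on the published qualitative contract for that scenario: the sparse joint
# model separates all three clusters while concatenated PCA cannot.
#
# Usage: Rscript scripts/calibrate_effect_size.R [n_replicates]

library(omiclust)
suppressPackageStartupMessages(library(dplyr))

args <- commandArgs(trailingOnly = TRUE)
n_rep <- if (length(args) >= 1) as.integer(args[[1]]) else 20L

kmeans_cv_error <- function(scenario, delta, n_rep, seed = 7L) {
  mean(vapply(seq_len(n_rep), function(r) {
    sim <- gen_scenario(scenario, seed = seed + r, delta = delta)
    mean(vapply(sim$dataset$types$type, function(tp) {
      as.numeric(cv_error_rate(
        subset_types(sim$dataset, tp), sim$true_labels,
        method = "kmeans", K = 2, n_folds = 5, seed = seed + r,
        scale = "center"))
    }, numeric(1)))
  }, numeric(1)))
}

calibrate <- function(scenario, target, grid, n_rep) {
  errs <- vapply(grid, function(d) kmeans_cv_error(scenario, d, n_rep), numeric(1))
  tab <- tibble(delta = grid, kmeans_cv_error = errs,
                abs_gap = abs(errs - target))
  print(tab)
  chosen <- tab$delta[which.min(tab$abs_gap)]
  cat(sprintf("%s: target %.2f -> chosen delta = %.2f\n\n", scenario, target, chosen))
  chosen
}

cat("== Scenario 1 (20 planted features; K-means baseline target error 0.08) ==\n")
d1 <- calibrate("scenario1", 0.08, seq(0.6, 1.2, by = 0.05), n_rep)

# Scenario 2's published baseline prints three anchors (correct-K 40%, CV
# error 0.11, RI 0.48) that no single delta reproduces simultaneously under
# this noise model; delta is chosen to minimise the combined discrepancy of
# the error and RI anchors, each scaled by the published scenario-1 SD of
# that quantity (0.04 and 0.18).  The correct-K anchor is insensitive to
# delta here and is excluded (see the methods vignette).
cat("== Scenario 2 (2 planted features; joint error/RI anchor) ==\n")
kmeans_ri <- function(scenario, delta, n_rep, seed = 7L) {
  mean(vapply(seq_len(n_rep), function(r) {
    sim <- gen_scenario(scenario, seed = seed + r, delta = delta)
    mean(vapply(sim$dataset$types$type, function(tp) {
      as.numeric(reproducibility_index(
        subset_types(sim$dataset, tp), K = 2, n_splits = 20,
        seed = seed + r, method = "kmeans", scale = "center"))
    }, numeric(1)))
  }, numeric(1)))
}
grid2 <- seq(2.75, 3.1, by = 0.05)
tab2 <- tibble(
  delta = grid2,
  kmeans_cv_error = vapply(grid2, function(d) kmeans_cv_error("scenario2", d, n_rep),
                           numeric(1)),
  kmeans_RI = vapply(grid2, function(d) kmeans_ri("scenario2", d, n_rep), numeric(1))
) |>
  mutate(G = abs(kmeans_cv_error - 0.11) / 0.04 + abs(kmeans_RI - 0.48) / 0.18)
print(tab2)
d2 <- tab2$delta[which.min(tab2$G)]
cat(sprintf("scenario2: chosen delta = %.2f\n\n", d2))

cat("== Three-cluster scenario (qualitative: joint model >> concatenated PCA) ==\n")
for (d in c(2.5, 3.0, 3.5)) {
  res <- vapply(seq_len(10), function(r) {
    sim <- gen_three_cluster(seed = 100 + r, delta = d)
    fit <- suppressWarnings(omiclust(sim$dataset, K = 3, penalties = 0.45,
                                     scale = "center", seed = r))
    pc <- pca_concat(sim$dataset, n_components = 2, K = 3, seed = r,
                     scale = "center")
    c(icl = adjusted_rand(fit$labels, sim$true_labels),
      pca = adjusted_rand(pc$labels, sim$true_labels))
  }, numeric(2))
  cat(sprintf("delta = %.1f  mean ARI: joint %.3f, PCA %.3f\n",
              d, mean(res["icl", ]), mean(res["pca", ])))
}

cat(sprintf("\nFrozen: scenario1 = %.2f, scenario2 = %.2f, three_cluster = 3.0\n",
            d1, d2))
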