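# Planted-cluster simulation generators and the benchmark harness.
#
# Effect sizes are expressed in within-cluster (noise) SD units.  The
# two-cluster defaults were frozen once by the shipped calibration script
# (scripts/calibrate_effect_size.R), which anchors the per-type K-means
# baseline to its published two-cluster benchmark behaviour; all benchmark
# and acceptance runs use these frozen values.

#' Default planted effect sizes for the simulation scenarios
#'
#' Named vector of the frozen between-cluster mean shifts (in noise-SD
#' units) used by the generators: see `scripts/calibrate_effect_size.R`
#' for how the two-cluster values were chosen.
#' @export
default_effect_sizes <- c(scenario1 = 0.90, scenario2 = 2.90, three_cluster = 3.0)

new_sim_study <- function(dataset, labels, true_features, params) {
  structure(list(dataset = dataset,
                 true_labels = labels,
                 true_features = true_features,
                 params = params),
            class = "omics_sim")
}

#' @export
print.omics_sim <- function(x, ...) {
  cat("<omics_sim> scenario: ", x$params$scenario, ", n = ",
      length(x$true_labels), ", K = ", length(unique(x$true_labels)),
      ", delta = ", x$params$delta, "\n", sep = "")
  print(x$dataset)
  invisible(x)
}

gen_two_cluster <- function(seed, delta, n_planted, scenario,
                            p = 200L, n = 100L, m = 2L) {
  withr::with_seed(as.integer(seed), {
    labels <- rep(1:2, each = n / 2)
    mats <- list(); feats <- list()
    for (t in seq_len(m)) {
      planted <- sort(sample(p, n_planted))
      X <- matrix(rnorm(p * n), p, n)
      shift <- delta * (labels - 1.5)      # -delta/2 vs +delta/2
      X[planted, ] <- X[planted, ] + rep(shift, each = n_planted)
      rownames(X) <- sprintf("t%d_f%03d", t, seq_len(p))
      colnames(X) <- sprintf("s%03d", seq_len(n))
      nm <- paste0("type", t)
      mats[[nm]] <- X
      feats[[nm]] <- planted
    }
    new_sim_study(omics_dataset(mats), setNames(labels, colnames(mats[[1]])),
                  feats,
                  list(scenario = scenario, delta = delta, K = 2L,
                       n_planted = n_planted, p = p, n = n, seed = seed))
  })
}

#' Simulate scenario 1: moderately sparse two-cluster structure
#'
#' A pair of matched data types, each with 200 features in 100 samples
#' split into two equal clusters.  In each type, 20 planted features carry
#' a between-cluster mean shift of `delta` noise-SD units (centred at
#' ±`delta/2`); the remaining 180 features are standard Gaussian noise.
#'
#' @param seed Integer seed; generation is a pure function of
#'   `(seed, delta)`.
#' @param delta Between-cluster mean shift in noise-SD units.
#' @return An `omics_sim` object: `dataset`, `true_labels`, per-type
#'   `true_features` (planted indices) and `params`.
#' @export
gen_scenario1 <- function(seed, delta = default_effect_sizes[["scenario1"]]) {
  gen_two_cluster(seed, delta, n_planted = 20L, scenario = "scenario1")
}

#' Simulate scenario 2: extremely sparse two-cluster structure
#'
#' Same shape as scenario 1 but only 2 cluster-associated features per data
#' type and 198 noise features.
#'
#' @inheritParams gen_scenario1
#' @return An `omics_sim` object.
#' @export
gen_scenario2 <- function(seed, delta = default_effect_sizes[["scenario2"]]) {
  gen_two_cluster(seed, delta, n_planted = 2L, scenario = "scenario2")
}

#' Simulate the three-cluster two-type scenario
#'
#' 150 samples in three equal clusters, two data types of 1,000 features
#' each.  A common set of 5 correlated features present in both types
#' (sharing one standard-normal latent draw per sample, loading 1)
#' separates cluster 1; another set of 5 correlated features specific to
#' type 2 separates cluster 2; cluster 3 is the background class and all
#' remaining features are noise.  Cluster 2 is therefore invisible in data
#' type 1 — no single type can recover all three clusters.
#'
#' @inheritParams gen_scenario1
#' @param p Features per data type.
#' @param n Total samples (three equal clusters).
#' @return An `omics_sim` object.
#' @export
gen_three_cluster <- function(seed, delta = default_effect_sizes[["three_cluster"]],
                              p = 1000L, n = 150L) {
  withr::with_seed(as.integer(seed), {
    labels <- rep(1:3, each = n / 3)
    shared <- sort(sample(p, 5))               # in both types, marks cluster 1
    specific <- sort(sample(setdiff(seq_len(p), shared), 5))  # type 2 only, cluster 2
    mk <- function(t) {
      X <- matrix(rnorm(p * n), p, n)
      X[shared, ] <- X[shared, ] + rep(delta * (labels == 1), each = 5)
      if (t == 2) {
        X[specific, ] <- X[specific, ] + rep(delta * (labels == 2), each = 5)
      }
      rownames(X) <- sprintf("t%d_f%04d", t, seq_len(p))
      colnames(X) <- sprintf("s%03d", seq_len(n))
      X
    }
    mats <- list(type1 = mk(1), type2 = mk(2))
    new_sim_study(omics_dataset(mats), setNames(labels, colnames(mats[[1]])),
                  list(type1 = shared, type2 = sort(c(shared, specific))),
                  list(scenario = "three_cluster", delta = delta, K = 3L,
                       p = p, n = n, seed = seed))
  })
}

#' Generate a simulated study by scenario name
#' @param scenario `"scenario1"`, `"scenario2"` or `"three_cluster"`.
#' @param seed Integer seed.
#' @param delta Optional effect-size override.
#' @return An `omics_sim` object.
#' @export
gen_scenario <- function(scenario = c("scenario1", "scenario2", "three_cluster"),
                         seed, delta = NULL) {
  scenario <- match.arg(scenario)
  gen <- switch(scenario, scenario1 = gen_scenario1, scenario2 = gen_scenario2,
                three_cluster = gen_three_cluster)
  if (is.null(delta)) gen(seed) else gen(seed, delta = delta)
}

#' Benchmark clustering methods on replicated simulations
#'
#' The machine twin of a methods-comparison table: for each replicate of a
#' simulation scenario it runs the requested methods and scores (i) whether
#' the method's model-selection criterion picks the planted number of
#' clusters, (ii) the cross-validated misclassification rate against the
#' planted labels at the true K, and (iii) the resampling reproducibility
#' index at the true K.  Per-type results of the separate K-means baseline
#' are averaged, matching the reporting convention for that method.
#'
#' For the two-cluster scenarios the integrative model's penalties are
#' tuned per replicate over a uniform design; for the three-cluster
#' scenario a fixed strong-sparsity penalty is used and a concatenated-PCA
#' comparison (label-recovery ARI on 2 components) is available via
#' `methods = "pca_concat"`.
#'
#' @param scenario `"scenario1"`, `"scenario2"` or `"three_cluster"`.
#' @param n_replicates Number of simulation replicates (SDs are `NA` when 1).
#' @param methods Any of `"icluster"`, `"separate_kmeans"`, `"pca_concat"`.
#' @param seed Integer seed; replicate r uses a seed derived from
#'   `seed + r`.
#' @param K_range Candidate K values for model selection.
#' @param n_trials Uniform-design points per K when tuning.
#' @param tune_splits RI splits used during tuning (coarse).
#' @param tune_max_iter EM iteration cap inside tuning fits (ranking
#'   penalty points does not need fully polished fits).
#' @param ri_splits RI splits used for the reported reproducibility index.
#' @param cv_folds Folds for the cross-validated error rate.
#' @param fixed_penalty Penalty used for the three-cluster scenario fits.
#' @param scale Standardization inside every fit; defaults to `"center"`
#'   because the generators already produce unit-SD noise, so rescaling
#'   per feature would only attenuate the planted effects.
#' @param delta Optional effect-size override passed to the generator.
#' @return An `omiclust_benchmark` tibble: one row per method with
#'   `freq_correct_K`, `mean_error`, `sd_error`, `mean_RI`, `sd_RI`;
#'   per-replicate details in attribute `"details"`.
#' @export
run_benchmark <- function(scenario = c("scenario1", "scenario2", "three_cluster"),
                          n_replicates = 50, methods = c("icluster", "separate_kmeans"),
                          seed = 1L, K_range = 2:4, n_trials = 8,
                          tune_splits = 8, tune_max_iter = 60,
                          ri_splits = 20, cv_folds = 5,
                          fixed_penalty = 0.45, delta = NULL,
                          scale = c("center", "zscore", "none")) {
  scale <- match.arg(scale)
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, c("icluster", "separate_kmeans", "pca_concat"),
                       several.ok = TRUE)
  details <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- child_seed(seed, r)
    sim <- gen_scenario(scenario, seed = rseed, delta = delta)
    true_K <- sim$params$K
    truth <- sim$true_labels
    for (mth in methods) {
      row <- switch(
        mth,
        icluster = {
          if (scenario == "three_cluster") {
            pens <- fixed_penalty
            chosen <- NA_integer_
          } else {
            tuned <- tune_omiclust(sim$dataset, K_range = K_range,
                                   n_trials = n_trials, n_splits = tune_splits,
                                   seed = child_seed(rseed, 2L), scale = scale,
                                   compute_pod = FALSE, max_iter = tune_max_iter)
            chosen <- recommended_k(tuned)$K
            bpk <- best_per_k(tuned)
            at_true <- bpk[bpk$K == true_K, ]
            pens <- setNames(
              as.numeric(at_true[paste0("penalty_", sim$dataset$types$type)]),
              sim$dataset$types$type)
          }
          err <- cv_error_rate(sim$dataset, truth, method = "omiclust",
                               K = true_K, penalties = pens, n_folds = cv_folds,
                               seed = child_seed(rseed, 3L), scale = scale)
          ri <- reproducibility_index(sim$dataset, K = true_K, penalties = pens,
                                      n_splits = ri_splits,
                                      seed = child_seed(rseed, 4L), scale = scale)
          ari <- if (scenario == "three_cluster") {
            fit <- suppressWarnings(omiclust(sim$dataset, K = true_K,
                                             penalties = pens, scale = scale,
                                             seed = child_seed(rseed, 5L)))
            adjusted_rand(fit$labels, truth)
          } else NA_real_
          tibble(method = "icluster", replicate = r,
                 chosen_K = as.integer(chosen),
                 correct_K = if (is.na(chosen)) NA else as.numeric(chosen == true_K),
                 error = as.numeric(err), RI = as.numeric(ri), ari = ari)
        },
        separate_kmeans = {
          base <- separate_kmeans(sim$dataset, K_range = K_range,
                                  n_splits = tune_splits,
                                  seed = child_seed(rseed, 6L), scale = scale)
          per_type <- map(sim$dataset$types$type, function(tp) {
            sub <- subset_types(sim$dataset, tp)
            err <- cv_error_rate(sub, truth, method = "kmeans", K = true_K,
                                 n_folds = cv_folds, scale = scale,
                                 seed = child_seed(rseed, 7L, match(tp, sim$dataset$types$type)))
            ri <- reproducibility_index(sub, K = true_K, n_splits = ri_splits,
                                        seed = child_seed(rseed, 8L, match(tp, sim$dataset$types$type)),
                                        method = "kmeans", scale = scale)
            tibble(correct = as.numeric(base$chosen_K[base$type == tp] == true_K),
                   error = as.numeric(err), RI = as.numeric(ri),
                   ari = adjusted_rand(baseline_labels(base)[[tp]], truth))
          })
          pt <- list_rbind(per_type)
          tibble(method = "separate_kmeans", replicate = r,
                 chosen_K = NA_integer_, correct_K = mean(pt$correct),
                 error = mean(pt$error), RI = mean(pt$RI), ari = mean(pt$ari))
        },
        pca_concat = {
          pc <- pca_concat(sim$dataset, n_components = true_K - 1L, K = true_K,
                           seed = child_seed(rseed, 9L), scale = scale)
          tibble(method = "pca_concat", replicate = r, chosen_K = NA_integer_,
                 correct_K = NA_real_, error = NA_real_, RI = NA_real_,
                 ari = adjusted_rand(pc$labels, truth))
        })
      details[[length(details) + 1L]] <- row
    }
  }
  details <- list_rbind(details)
  summary <- details |>
    group_by(.data$method) |>
    summarise(
      n_replicates = n(),
      freq_correct_K = mean(.data$correct_K),
      mean_error = mean(.data$error),
      sd_error = if (n() > 1) sd(.data$error) else NA_real_,
      mean_RI = mean(.data$RI),
      sd_RI = if (n() > 1) sd(.data$RI) else NA_real_,
      mean_ari = mean(.data$ari),
      .groups = "drop"
    )
  structure(summary, class = c("omiclust_benchmark", class(summary)),
            details = details, scenario = scenario, seed = seed)
}

#' Per-replicate details of a benchmark run
#' @param x An `omiclust_benchmark` object.
#' @return Tibble of per-replicate, per-method results.
#' @export
benchmark_details <- function(x) attr(x, "details")
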