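# Comparison methods: per-type K-means with RI-based choice of K, and
# naive integration by PCA on the concatenated matrix.

#' Separate per-type K-means clustering
#'
#' The conventional workflow that the integrative model is benchmarked
#' against: each data type is clustered on its own by K-means, with the
#' number of clusters chosen by the same resampling reproducibility
#' criterion restricted to that type.
#'
#' @param dataset An [omics_dataset()] (or coercible).
#' @param K_range Candidate numbers of clusters (default `2:4`).
#' @param n_splits Learning/test splits per RI evaluation.
#' @param seed Seed for splits and K-means restarts.
#' @param scale Standardization mode applied per type before clustering.
#' @return An `omiclust_baseline` object: a tibble with one row per data
#'   type (`type`, `chosen_K`, `RI`) and a `labels` attribute holding the
#'   per-type label vectors at the chosen K.
#' @export
separate_kmeans <- function(dataset, K_range = 2:4, n_splits = 20, seed = 1L,
                            scale = c("zscore", "center", "none")) {
  scale <- match.arg(scale)
  dataset <- as_omics_dataset(dataset)
  types <- dataset$types$type
  rows <- list(); labels <- list()
  for (tp in types) {
    sub <- subset_types(dataset, tp)
    ris <- vapply(K_range, function(K) {
      as.numeric(reproducibility_index(sub, K = K, n_splits = n_splits,
                                       seed = child_seed(seed, match(tp, types), K),
                                       method = "kmeans", scale = scale))
    }, numeric(1))
    chosen <- K_range[order(-ris, K_range)][1]
    X <- t(stack_dataset(standardize(sub, mode = scale))$X)
    km <- withr::with_seed(child_seed(seed, match(tp, types)),
                           kmeans(X, centers = chosen, nstart = 20, iter.max = 100))
    labels[[tp]] <- relabel_by_first_occurrence(km$cluster)
    rows[[tp]] <- tibble(type = tp, chosen_K = as.integer(chosen),
                         RI = ris[match(chosen, K_range)])
  }
  structure(list_rbind(unname(rows)),
            class = c("omiclust_baseline", "tbl_df", "tbl", "data.frame"),
            labels = labels, method = "separate_kmeans", seed = seed)
}

#' Per-type labels of a baseline result
#' @param x An `omiclust_baseline` object.
#' @return Named list of integer label vectors, one per data type.
#' @export
baseline_labels <- function(x) attr(x, "labels")

#' Naive integration: PCA on the concatenated data matrix
#'
#' Standardizes each data type, row-concatenates all types into one matrix
#' and takes the leading principal components of the samples; optionally
#' clusters the samples by K-means on those scores.  This is the "combine
#' and rotate" baseline the joint model is compared with.
#'
#' @param dataset An [omics_dataset()] (or coercible).
#' @param n_components Number of principal components to keep.
#' @param K Optional number of clusters; when given, K-means labels on the
#'   scores are returned.
#' @param seed Seed for the K-means step.
#' @param scale Standardization mode applied per type before concatenation.
#' @return An `omiclust_pca` object: list with `scores` (tibble of sample
#'   coordinates), `variance_explained`, and `labels` (or `NULL`).
#' @export
pca_concat <- function(dataset, n_components = 2, K = NULL, seed = 1L,
                       scale = c("zscore", "center", "none")) {
  dataset <- as_omics_dataset(dataset)
  X <- stack_dataset(standardize(dataset, mode = match.arg(scale)))$X
  n_components <- min(n_components, nrow(X), ncol(X) - 1L)
  pc <- prcomp(t(X), center = FALSE, scale. = FALSE, rank. = n_components)
  if (ncol(pc$x) < n_components) {
    warn(sprintf("Rank deficiency: only %d component(s) available.", ncol(pc$x)))
  }
  scores <- as_tibble(pc$x[, seq_len(ncol(pc$x)), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = dataset$sample_ids), scores)
  labels <- NULL
  if (!is.null(K)) {
    km <- withr::with_seed(as.integer(seed),
                           kmeans(pc$x, centers = K, nstart = 20, iter.max = 100))
    labels <- setNames(relabel_by_first_occurrence(km$cluster), dataset$sample_ids)
  }
  structure(list(scores = scores,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2),
                 labels = labels, n_components = ncol(pc$x)),
            class = "omiclust_pca")
}

#' Align predicted cluster labels with reference labels
#'
#' Finds the one-to-one mapping of predicted clusters onto reference
#' clusters that minimizes the number of disagreements (optimal assignment,
#' found by exhaustive permutation search — cluster counts are small).
#' When the two label sets have different sizes, the smaller set is mapped
#' injectively into the larger and unmatched samples count as errors.
#'
#' @param pred,truth Label vectors of equal length.
#' @return List with `mapped` (pred relabelled into truth's labels),
#'   `errors` (count of disagreements after alignment) and `error_rate`.
#' @export
align_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("Label vectors must have equal length.")
  up <- sort(unique(pred)); ut <- sort(unique(truth))
  kp <- length(up); kt <- length(ut)
  big <- max(kp, kt)
  if (big > 7) abort("Too many clusters for exhaustive label alignment.")
  # cost[i, j]: samples in pred-cluster i not in truth-cluster j
  cost <- matrix(0, kp, kt)
  for (i in seq_len(kp)) for (j in seq_len(kt)) {
    cost[i, j] <- sum(pred == up[i] & truth != ut[j])
  }
  unmatched_cost <- vapply(seq_len(kp), function(i) sum(pred == up[i]), numeric(1))
  best <- NULL; best_cost <- Inf
  for (perm in all_permutations(big)) {
    # perm maps slot i -> slot perm[i]; interpret on the padded square problem
    total <- 0
    map_ij <- rep(NA_integer_, kp)
    for (i in seq_len(kp)) {
      j <- perm[i]
      if (j <= kt) { total <- total + cost[i, j]; map_ij[i] <- j }
      else total <- total + unmatched_cost[i]
    }
    if (total < best_cost) { best_cost <- total; best <- map_ij }
  }
  mapped <- rep(NA, length(pred))
  for (i in seq_len(kp)) {
    if (!is.na(best[i])) mapped[pred == up[i]] <- ut[best[i]]
  }
  list(mapped = mapped, errors = best_cost, error_rate = best_cost / length(pred))
}

#' Cross-validated misclassification rate against known labels
#'
#' Splits the samples into folds; for each fold the chosen clustering
#' method is trained on the remaining samples and the held-out samples'
#' labels are predicted (nearest centroid in the method's latent or feature
#' space).  Predicted labels are aligned to the reference labels by optimal
#' assignment within each fold and the misclassification fraction is
#' averaged over folds.  Intended for simulations where planted labels
#' exist.
#'
#' @param dataset An [omics_dataset()] (or coercible).
#' @param true_labels Reference labels of length `n`.
#' @param method `"omiclust"` or `"kmeans"` (the latter on the stacked
#'   matrix — pass a single-type dataset for a per-type baseline).
#' @param K Number of clusters to fit.
#' @param penalties Penalties for the integrative model.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for fold assignment and fits.
#' @param scale Standardization mode used inside every nested fit.
#' @param ... Passed to [omiclust()].
#' @return Mean misclassification rate, with per-fold rates in attribute
#'   `"folds"`.
#' @export
cv_error_rate <- function(dataset, true_labels, method = c("omiclust", "kmeans"),
                          K, penalties = 0.5, n_folds = 5, seed = 1L,
                          scale = c("zscore", "center", "none"), ...) {
  dataset <- as_omics_dataset(dataset)
  method <- match.arg(method)
  scale <- match.arg(scale)
  n <- n_samples(dataset)
  if (length(true_labels) != n) abort("`true_labels` length must be n.")
  fold_id <- withr::with_seed(child_seed(seed, 1L),
                              sample(rep(seq_len(n_folds), length.out = n)))
  rates <- vapply(seq_len(n_folds), function(f) {
    test_idx <- which(fold_id == f)
    train <- subset_samples(dataset, -test_idx)
    test <- subset_samples(dataset, test_idx)
    if (method == "omiclust") {
      fit <- suppressWarnings(
        omiclust(train, K = K, penalties = penalties, scale = scale,
                 seed = child_seed(seed, f, 2L), trace_loglik = FALSE, ...))
      pred <- predict(fit, test)$cluster
    } else {
      train_std <- standardize(train, mode = scale)
      Xl <- t(stack_dataset(train_std)$X)
      std <- attr(train_std, "standardization")
      Xt <- t(stack_dataset(apply_standardization(test, std))$X)
      km <- withr::with_seed(child_seed(seed, f, 2L),
                             kmeans(Xl, centers = K, nstart = 20, iter.max = 100))
      d2 <- vapply(seq_len(K), function(k) {
        rowSums((Xt - matrix(km$centers[k, ], nrow(Xt), ncol(Xt), byrow = TRUE))^2)
      }, numeric(nrow(Xt)))
      pred <- max.col(-matrix(d2, ncol = K))
    }
    align_labels(pred, true_labels[test_idx])$error_rate
  }, numeric(1))
  w <- tabulate(fold_id, n_folds) / n
  structure(sum(rates * w), folds = rates)
}
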