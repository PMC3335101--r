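# Single-data-type validation (k-NN) and mutual-information enrichment.

#' Mutual information of a bivariate Gaussian pair
#'
#' For jointly Gaussian variables with correlation `rho`, the mutual
#' information has the closed form `-0.5 * log(1 - rho^2)` (natural log,
#' so the result is in nats).  It is zero iff `rho = 0` and strictly
#' increasing in `|rho|`.
#'
#' @param rho Correlation(s) with `|rho| < 1`.
#' @return Mutual information in nats, same length as `rho`.
#' @examples
#' gaussian_mi(0)      # 0
#' gaussian_mi(0.8)
#' @export
gaussian_mi <- function(rho) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    abort("`rho` must satisfy |rho| < 1 (mutual information is infinite at |rho| = 1).")
  }
  -0.5 * log(1 - rho^2)
}

#' Mutual-information enrichment of a selected feature set
#'
#' Pairs features of two data types (by shared feature identifier, or an
#' explicit pairing), computes each pair's Pearson correlation across
#' samples and converts it to Gaussian mutual information, then compares
#' the MI distribution of the selected pairs against the rest with a
#' one-sided rank test for a rightward location shift.  A feature-selection
#' that captures coordinated regulation across data types shows a selected
#' distribution shifted toward high MI.
#'
#' @param dataA,dataB Feature-by-sample matrices on the same samples.
#' @param selected Character vector of selected pair identifiers.
#' @param pairing Optional two-column data frame (`feature_a`, `feature_b`);
#'   by default features with identical identifiers are paired.
#' @return An `omiclust_mi` tibble with `pair`, `rho`, `mi` and `selected`,
#'   plus a `shift_test` attribute (one-sided Wilcoxon selected > rest).
#' @export
mi_enrichment <- function(dataA, dataB, selected = character(), pairing = NULL) {
  dataA <- as.matrix(dataA); dataB <- as.matrix(dataB)
  if (ncol(dataA) != ncol(dataB)) abort("Data types must share their samples.")
  if (is.null(pairing)) {
    common <- intersect(rownames(dataA), rownames(dataB))
    if (length(common) == 0) abort("No shared feature identifiers to pair on.")
    pairing <- tibble(feature_a = common, feature_b = common, pair = common)
  } else {
    pairing <- as_tibble(pairing)
    if (!all(c("feature_a", "feature_b") %in% names(pairing))) {
      abort("`pairing` needs columns `feature_a` and `feature_b`.")
    }
    if (is.null(pairing$pair)) {
      pairing$pair <- paste(pairing$feature_a, pairing$feature_b, sep = ":")
    }
  }
  rows <- pmap(pairing, function(feature_a, feature_b, pair) {
    xa <- dataA[feature_a, ]; xb <- dataB[feature_b, ]
    if (sd(xa) == 0 || sd(xb) == 0) {
      inform(sprintf("Skipping constant-feature pair '%s'.", pair))
      return(NULL)
    }
    r <- cor(xa, xb)
    r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
    tibble(pair = pair, rho = r, mi = gaussian_mi(r))
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  out$selected <- out$pair %in% selected
  test <- NULL
  if (any(out$selected) && any(!out$selected)) {
    test <- wilcox.test(out$mi[out$selected], out$mi[!out$selected],
                        alternative = "greater", exact = FALSE)
  }
  structure(out, class = c("omiclust_mi", class(out)), shift_test = test)
}

#' @export
glance.omiclust_mi <- function(x, ...) {
  test <- attr(x, "shift_test")
  tibble(n_pairs = nrow(x), n_selected = sum(x$selected),
         median_mi_selected = stats::median(x$mi[x$selected]),
         median_mi_rest = stats::median(x$mi[!x$selected]),
         shift_statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
         shift_p_value = if (is.null(test)) NA_real_ else test$p.value)
}

#' Plot mutual-information distributions of selected vs all features
#' @param object An `omiclust_mi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omiclust_mi <- function(object, ...) {
  df <- dplyr::bind_rows(
    mutate(as_tibble(object), group = "all pairs"),
    mutate(filter(as_tibble(object), .data$selected), group = "selected")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mi, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Mutual information (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

# k nearest training neighbours of each query row, deterministic:
# distance ties broken by training-sample order
knn_votes <- function(train, query, train_labels, k) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(query)), rowSums(train^2)) -
    2 * tcrossprod(query, train)
  ul <- sort(unique(as.integer(train_labels)))
  apply(d2, 1, function(di) {
    nb <- order(di)[seq_len(k)]               # order() is stable: ties by index
    cnt <- vapply(ul, function(l) sum(train_labels[nb] == l), integer(1))
    ul[which.max(cnt)]                        # vote ties: lowest label wins
  })
}

#' Leave-one-out k-NN reproduction of cluster labels from one data type
#'
#' For each candidate `k`, classifies every sample from its `k` nearest
#' neighbours (Euclidean distance on the supplied feature profile, majority
#' vote) with that sample left out, and reports the misclassification rate
#' against the supplied labels.  Used to ask how well a single data type
#' alone can reproduce integrated cluster membership.
#'
#' @param features Numeric matrix or data frame, samples in rows.
#' @param labels Integer cluster labels, length `nrow(features)`.
#' @param k_range Candidate neighbourhood sizes; `k >= n` entries are
#'   skipped.
#' @return List with `best_k` (smallest error, ties to the smaller k),
#'   `cv_error`, and `errors` (tibble of k vs error).
#' @examples
#' x <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), ncol = 2, byrow = TRUE)
#' knn_loocv(x, c(1, 1, 2, 2), k_range = 1:3)
#' @export
knn_loocv <- function(features, labels, k_range = 1:10) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) abort("At least 3 samples are required.")
  if (length(labels) != n) abort("`labels` length must match the sample count.")
  labels <- as.integer(labels)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & k_range < n]
  if (length(k_range) == 0) abort("No usable k in `k_range` (need 1 <= k < n).")
  errs <- vapply(k_range, function(k) {
    pred <- vapply(seq_len(n), function(i) {
      knn_votes(features[-i, , drop = FALSE], features[i, , drop = FALSE],
                labels[-i], k)
    }, integer(1))
    mean(pred != labels)
  }, numeric(1))
  best <- which.min(errs)                     # which.min ties -> smallest k
  list(best_k = k_range[best], cv_error = errs[best],
       errors = tibble(k = k_range, error = errs))
}

#' Transfer cluster labels to new samples by k-NN majority vote
#'
#' Assigns each new sample the majority label among its `k` nearest
#' training samples (Euclidean distance).  Distance ties are broken by
#' training-sample order and vote ties by the lowest cluster index, so the
#' assignment is deterministic.
#'
#' @param train_features Numeric matrix, training samples in rows.
#' @param train_labels Integer labels for the training samples.
#' @param new_features Numeric matrix of query samples (same columns).
#' @param k Neighbourhood size (`1 <= k <= n_train`).
#' @return Integer label vector for the query samples.
#' @export
knn_transfer <- function(train_features, train_labels, new_features, k) {
  train_features <- as.matrix(train_features)
  new_features <- as.matrix(new_features)
  if (ncol(train_features) != ncol(new_features)) {
    abort("Training and query features must have the same columns.")
  }
  if (k < 1 || k > nrow(train_features)) {
    abort("`k` must be between 1 and the number of training samples.")
  }
  knn_votes(train_features, new_features, as.integer(train_labels), as.integer(k))
}
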