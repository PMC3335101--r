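#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples
#' (Hubert–Arabie form).  Equals 1 when the partitions are identical up to
#' relabelling and has expectation 0 for independent random partitions.
#'
#' @param labels_a,labels_b Vectors of cluster labels of equal length >= 2.
#' @return A single number <= 1.
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have the same length.")
  }
  n <- length(labels_a)
  if (n < 2) abort("At least two samples are required.")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / (maximum - expected)
}

#' Cluster separability: proportion of deviation from a block structure
#'
#' Builds the product matrix of the posterior factor means,
#' `S0 = E[Z]' E[Z]`, min–max maps it to `[0, 1]`, sorts the samples by
#' cluster label and measures the mean absolute deviation from the ideal
#' block-diagonal matrix (within-cluster blocks of ones, off-diagonal
#' blocks of zeros).  Perfectly separated clusters give POD = 0; values
#' near 1 indicate no block structure.
#'
#' @param posterior_mean `q x n` matrix of posterior factor means (or any
#'   latent coordinates with samples in columns).
#' @param labels Cluster labels of length `n`.
#' @return A single number in `[0, 1]`.
#' @export
pod <- function(posterior_mean, labels) {
  pm <- as.matrix(posterior_mean)
  n <- ncol(pm)
  if (length(labels) != n) abort("`labels` length must match the sample count.")
  ord <- order(labels)
  S0 <- crossprod(pm[, ord, drop = FALSE])
  rng <- range(S0)
  S <- if (diff(rng) <= .Machine$double.eps * 100) {
    matrix(0.5, n, n)
  } else {
    (S0 - rng[1]) / diff(rng)
  }
  ideal <- outer(labels[ord], labels[ord], `==`) * 1
  mean(abs(S - ideal))
}

# good-lattice-point generating vectors (first component always 1);
# 2-d vectors are the Fibonacci lattices, 3-d vectors were chosen by a
# one-off centered-L2-discrepancy search over coprime candidates
glp_vectors <- list(
  `2` = list(`5` = c(1L, 2L), `8` = c(1L, 5L), `13` = c(1L, 5L),
             `21` = c(1L, 13L), `34` = c(1L, 25L)),
  `3` = list(`8` = c(1L, 3L, 5L), `13` = c(1L, 4L, 6L),
             `21` = c(1L, 4L, 5L), `34` = c(1L, 15L, 21L))
)

#' Uniform-design sample of the penalty domain
#'
#' Generates `n_trials` points scattered uniformly over the unit hypercube
#' `[0,1]^n_dims` with the Latin-hypercube property that every coordinate
#' takes each of the `n_trials` centred levels `(2i-1)/(2 n_trials)`
#' exactly once.  Uses number-theoretic good-lattice-point constructions
#' for tabulated sizes and falls back to a seeded maximin Latin hypercube
#' (snapped to the centred levels) otherwise.  Unlike a grid search, no two
#' trials share a coordinate value, so the design fills the space without
#' wasted near-duplicate fits.
#'
#' @param n_trials Number of design points (>= 1).
#' @param n_dims Dimension of the domain (number of penalty parameters).
#' @return An `n_trials x n_dims` matrix with values in `(0, 1)`.
#' @examples
#' uniform_design(8, 2)
#' @export
uniform_design <- function(n_trials, n_dims) {
  if (!is.numeric(n_trials) || n_trials < 1) abort("`n_trials` must be >= 1.")
  n_trials <- as.integer(n_trials)
  n_dims <- as.integer(n_dims)
  if (n_dims < 1) abort("`n_dims` must be >= 1.")
  if (n_trials < n_dims) {
    warn("Fewer trials than dimensions; the design cannot be space-filling.")
  }
  levels_of <- function(i, h) ((i * h - 0.5) / n_trials) %% 1
  if (n_dims == 1L) {
    return(matrix(levels_of(seq_len(n_trials), 1L), ncol = 1))
  }
  h <- glp_vectors[[as.character(n_dims)]][[as.character(n_trials)]]
  if (!is.null(h)) {
    out <- vapply(h, function(hk) levels_of(seq_len(n_trials), hk),
                  numeric(n_trials))
    return(matrix(out, nrow = n_trials))
  }
  # fallback: maximin LHS snapped to the centred levels (deterministic)
  raw <- withr::with_seed(20240401L + n_trials,
                          lhs::maximinLHS(n_trials, n_dims))
  snapped <- apply(raw, 2, function(col) (2 * rank(col, ties.method = "first") - 1) /
                     (2 * n_trials))
  matrix(snapped, nrow = n_trials)
}

#' Resampling-based cluster reproducibility index
#'
#' Repeatedly splits the samples into a learning and a test set.  For each
#' split the model is fit on the learning half, test-set labels are
#' predicted by projecting the test samples through the learned loadings
#' and assigning each to the nearest learned centroid, the model is refit
#' on the test half ("observed" labels), and the adjusted Rand index
#' between predicted and observed labels is recorded.  RI is the mean over
#' splits: values near 1 mean the clustering reproduces under resampling,
#' values near 0 mean it does not.
#'
#' @param dataset An [omics_dataset()] (or coercible).
#' @param K Number of clusters.
#' @param penalties Per-type penalties in `[0,1]` (ignored for
#'   `method = "kmeans"`).
#' @param n_splits Number of learning/test splits (default 20).
#' @param split_fraction Fraction of samples in the learning set (default 1/2).
#' @param seed Seed controlling the splits and all nested fits.
#' @param scale Standardization mode used inside every nested fit.
#' @param method `"omiclust"` for the integrative model or `"kmeans"` for a
#'   plain K-means on the stacked (single-type) data — the latter is what
#'   the per-type baseline uses so both methods face the same criterion.
#' @param ... Further arguments passed to [omiclust()] (e.g. `max_iter`).
#' @return Mean adjusted Rand index across splits, with the per-split
#'   values in attribute `"splits"`.
#' @export
reproducibility_index <- function(dataset, K, penalties = 0.5, n_splits = 20,
                                  split_fraction = 0.5, seed = 1L,
                                  method = c("omiclust", "kmeans"),
                                  scale = c("zscore", "center", "none"), ...) {
  dataset <- as_omics_dataset(dataset)
  method <- match.arg(method)
  scale <- match.arg(scale)
  n <- n_samples(dataset)
  n_learn <- max(K + 1L, floor(n * split_fraction))
  if (n_learn >= n - K) abort("Too few samples for a learning/test split at this K.")
  aris <- vapply(seq_len(n_splits), function(b) {
    idx <- withr::with_seed(child_seed(seed, b), sample(n, n_learn))
    learn <- subset_samples(dataset, idx)
    test <- subset_samples(dataset, -idx)
    if (method == "omiclust") {
      f_learn <- suppressWarnings(
        omiclust(learn, K = K, penalties = penalties, scale = scale,
                 seed = child_seed(seed, b, 2L), trace_loglik = FALSE, ...))
      pred <- predict(f_learn, test)$cluster
      f_test <- suppressWarnings(
        omiclust(test, K = K, penalties = penalties, scale = scale,
                 seed = child_seed(seed, b, 3L), trace_loglik = FALSE, ...))
      obs <- f_test$labels
    } else {
      learn_std <- standardize(learn, mode = scale)
      Xl <- t(stack_dataset(learn_std)$X)
      Xt_std <- apply_standardization(test, attr(learn_std, "standardization"))
      Xt <- t(stack_dataset(Xt_std)$X)
      km_l <- withr::with_seed(child_seed(seed, b, 2L),
                               kmeans(Xl, centers = K, nstart = 20, iter.max = 100))
      d2 <- vapply(seq_len(K), function(k) {
        rowSums((Xt - matrix(km_l$centers[k, ], nrow(Xt), ncol(Xt), byrow = TRUE))^2)
      }, numeric(nrow(Xt)))
      pred <- max.col(-matrix(d2, ncol = K))
      obs <- withr::with_seed(child_seed(seed, b, 3L),
                              kmeans(t(stack_dataset(standardize(test, mode = scale))$X),
                                     centers = K, nstart = 20, iter.max = 100))$cluster
    }
    adjusted_rand(pred, obs)
  }, numeric(1))
  structure(mean(aris), splits = aris)
}

#' Tune K and the per-type penalties by reproducibility and separability
#'
#' For every candidate `K`, evaluates the reproducibility index at
#' `n_trials` penalty vectors sampled by [uniform_design()] over the
#' per-type penalty cube, and records the POD separability and per-type
#' selected-feature counts of the full-data fit at each point.  The
#' recommended `K` maximizes the best per-K RI, with ties broken by
#' smaller POD and then by smaller `K`.
#'
#' @param dataset An [omics_dataset()] (or coercible).
#' @param K_range Candidate numbers of clusters (default `2:4`).
#' @param n_trials Number of uniform-design penalty points per K (default 8).
#' @param n_splits Learning/test splits per RI evaluation (default 5; a
#'   coarse setting adequate for ranking — recompute the RI of the chosen
#'   point with more splits for reporting).
#' @param seed Seed for all nested resampling and fits.
#' @param compute_pod Also fit the full data at every point to record POD
#'   and selected-feature counts (default `TRUE`; skipping them makes large
#'   tuning sweeps considerably cheaper, with RI ties then broken by K).
#' @param ... Passed on to [omiclust()] / [reproducibility_index()].
#' @return An `omiclust_tune` object: a tibble with one row per `(K, trial)`
#'   — penalty columns, `RI`, `POD`, selected counts — plus a
#'   `recommendation` attribute (list with `K` and `penalties`).
#' @examples
#' \donttest{
#' sim <- gen_scenario1(seed = 1)
#' tuned <- tune_omiclust(sim$dataset, K_range = 2:3, n_trials = 5, seed = 1)
#' recommended_k(tuned)
#' }
#' @export
tune_omiclust <- function(dataset, K_range = 2:4, n_trials = 8, n_splits = 5,
                          seed = 1L, compute_pod = TRUE, ...) {
  dataset <- as_omics_dataset(dataset)
  m <- length(dataset$matrices)
  types <- dataset$types$type
  design <- uniform_design(n_trials, m)
  grid <- tidyr::expand_grid(K = as.integer(K_range), trial = seq_len(n_trials))
  records <- pmap(grid, function(K, trial) {
    pen <- setNames(design[trial, ], types)
    rec <- tryCatch({
      ri <- reproducibility_index(dataset, K = K, penalties = pen,
                                  n_splits = n_splits,
                                  seed = child_seed(seed, K, trial), ...)
      if (compute_pod) {
        full <- suppressWarnings(
          omiclust(dataset, K = K, penalties = pen,
                   seed = child_seed(seed, K, trial, 5L), ...))
        cnt <- attr(selected_features(full), "counts")
        pod_val <- pod(full$posterior_mean, full$labels)
      } else {
        cnt <- rep(NA_integer_, length(types))
        pod_val <- NA_real_
      }
      c(list(K = K, trial = trial), as.list(setNames(pen, paste0("penalty_", types))),
        list(RI = as.numeric(ri), POD = pod_val),
        as.list(setNames(as.integer(cnt), paste0("n_selected_", types))),
        list(failed = FALSE))
    }, error = function(e) {
      warn(sprintf("Tuning point (K=%d, trial %d) failed: %s", K, trial,
                   conditionMessage(e)))
      c(list(K = K, trial = trial),
        as.list(setNames(pen, paste0("penalty_", types))),
        list(RI = NA_real_, POD = NA_real_, failed = TRUE))
    })
    as_tibble(rec)
  })
  out <- list_rbind(records)
  best_per_k <- out |>
    filter(!.data$failed) |>
    group_by(.data$K) |>
    arrange(dplyr::desc(.data$RI), .data$POD, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(dplyr::desc(.data$RI), .data$POD, .data$K)
  if (nrow(best_per_k) == 0) abort("All tuning points failed.")
  best <- best_per_k[1, ]
  rec <- list(
    K = best$K,
    penalties = setNames(as.numeric(best[paste0("penalty_", types)]), types),
    RI = best$RI, POD = best$POD
  )
  structure(out, class = c("omiclust_tune", class(out)),
            recommendation = rec, best_per_k = best_per_k, seed = seed)
}

#' Recommended number of clusters from a tuning run
#' @param x An `omiclust_tune` object.
#' @return The recommendation list (`K`, `penalties`, `RI`, `POD`).
#' @export
recommended_k <- function(x) attr(x, "recommendation")

#' Best tuning record for each candidate K
#' @param x An `omiclust_tune` object.
#' @return A tibble with one row per K (its best penalty point).
#' @export
best_per_k <- function(x) attr(x, "best_per_k")

#' @export
tidy.omiclust_tune <- function(x, ...) as_tibble(x)

#' @export
glance.omiclust_tune <- function(x, ...) {
  rec <- attr(x, "recommendation")
  tibble(K = rec$K, RI = rec$RI, POD = rec$POD,
         !!!setNames(as.list(rec$penalties), paste0("penalty_", names(rec$penalties))))
}

#' Plot reproducibility and separability across candidate K
#'
#' Shows each candidate K's best reproducibility index alongside the POD
#' separability of the same point; good solutions combine high RI with low
#' POD.
#'
#' @param object An `omiclust_tune` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omiclust_tune <- function(object, ...) {
  df <- best_per_k(object) |>
    select("K", "RI", "POD") |>
    tidyr::pivot_longer(c("RI", "POD"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters K", y = NULL) +
    ggplot2::theme_minimal()
}
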