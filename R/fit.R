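#' Fit the sparse joint latent-variable clustering model
#'
#' Projects all data types onto a shared latent subspace of dimension
#' `K - 1` by EM, applying (variance-weighted) soft-thresholding to the
#' loading update at every iteration so that noninformative features get
#' exactly-zero loadings.  Cluster labels are obtained by K-means on the
#' posterior means of the latent factors.
#'
#' @param data An [omics_dataset()], named list of matrices, or single matrix.
#' @param K Number of clusters (>= 2); the model uses `K - 1` latent factors.
#' @param penalties Per-type sparsity level in `[0, 1]` (recycled): 0 selects
#'   no features (null model), 1 keeps all features.
#' @param weighted Use the variance-weighted penalty (default `TRUE`); set
#'   `FALSE` for the plain lasso threshold.
#' @param scale Per-type feature standardization applied before fitting.
#' @param max_iter,tol EM stops when the largest absolute parameter change
#'   drops below `tol` (default `1e-4`) or after `max_iter` iterations
#'   (default 200), whichever comes first.
#' @param var_floor Lower bound on residual variances.
#' @param isotropic Constrain the residual variances to be equal within each
#'   data type (the probabilistic-PCA limit when a single type is fit with
#'   `penalties = 1`).
#' @param seed Seed for the K-means cluster assignment.
#' @param nstart K-means restarts for the assignment step.
#' @param trace_loglik Record the observed-data log-likelihood every
#'   iteration (skipped inside resampling loops for speed).
#'
#' @return An object of class `omiclust_fit` with loadings per type,
#'   residual variances, posterior factor moments, cluster `labels`,
#'   a per-iteration log-likelihood trace and convergence information.
#'   Methods: [predict.omiclust_fit()], [tidy()], [glance()], [autoplot()].
#' @examples
#' sim <- gen_scenario1(seed = 1)
#' fit <- omiclust(sim$dataset, K = 2, penalties = 0.5, seed = 1)
#' glance(fit)
#' @export
omiclust <- function(data, K, penalties = 0.5, weighted = TRUE,
                     scale = c("zscore", "center", "none"),
                     max_iter = 200, tol = 1e-4, var_floor = 1e-6,
                     isotropic = FALSE, seed = 1L, nstart = 20,
                     trace_loglik = TRUE) {
  dataset <- as_omics_dataset(data)
  scale <- match.arg(scale)
  if (!is.numeric(K) || length(K) != 1L || K < 2) abort("`K` must be an integer >= 2.")
  K <- as.integer(K)
  n <- n_samples(dataset)
  if (K >= n) abort(sprintf("K = %d must be smaller than the sample count n = %d.", K, n))
  m <- length(dataset$matrices)
  penalties <- rep_len(penalties, m)
  names(penalties) <- dataset$types$type
  if (any(penalties < 0 | penalties > 1)) abort("Penalties must lie in [0, 1].")

  std_data <- standardize(dataset, mode = scale)
  stk <- stack_dataset(std_data)
  X <- stk$X
  p <- nrow(X)
  q <- K - 1L

  # deterministic initialization: truncated SVD of the standardized stack
  sv <- svd(X, nu = q, nv = 0)
  B <- sv$u[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  flip <- apply(B, 2, function(b) sign(b[which.max(abs(b))]))
  B <- sweep(B, 2, ifelse(flip == 0, 1, flip), `*`)
  psi <- pmax(rowMeans(X^2) - rowSums(B^2), 1e-3)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- em_e_step(B, psi, X)
    ms <- em_m_step(X, es$mean, es$cov, stk$type_index, penalties, psi,
                    weighted = weighted, var_floor = var_floor)
    psi_new <- ms$psi
    if (isotropic) {
      for (tp in stk$types) {
        idx <- stk$type_index == tp
        psi_new[idx] <- mean(psi_new[idx])
      }
      psi_new <- pmax(psi_new, var_floor)
    }
    delta <- max(abs(ms$B - B), abs(psi_new - psi))
    B <- ms$B
    psi <- psi_new
    if (trace_loglik) loglik <- c(loglik, factor_model_loglik(B, psi, X))
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations (last change %.3g).",
                 max_iter, delta))
  }

  es <- em_e_step(B, psi, X)
  null_model <- all(B == 0)
  if (null_model) {
    warn("All loadings shrunk to zero (null model); all samples assigned to one cluster.")
    labels <- setNames(rep(1L, n), dataset$sample_ids)
    centers <- matrix(0, q, 1)
  } else {
    labels <- assign_clusters(es$mean, K, seed = seed, nstart = nstart)
    names(labels) <- dataset$sample_ids
    centers <- matrix(vapply(seq_len(K), function(k) {
      rowMeans(es$mean[, labels == k, drop = FALSE])
    }, numeric(q)), nrow = q)
  }

  rows <- split(seq_len(p), factor(stk$type_index, levels = stk$types))
  loadings <- map(rows, function(i) {
    out <- B[i, , drop = FALSE]
    rownames(out) <- rownames(X)[i]
    out
  })
  psi_by_type <- map(rows, function(i) setNames(psi[i], rownames(X)[i]))

  structure(
    list(
      K = K, n_factors = q, n = n,
      loadings = loadings, psi = psi_by_type,
      penalties = penalties, weighted = weighted,
      posterior_mean = `colnames<-`(es$mean, dataset$sample_ids),
      posterior_cov = es$cov,
      labels = labels, centers = centers,
      loglik_trace = loglik, converged = converged, n_iter = iter,
      standardization = attr(std_data, "standardization"),
      types = stk$types, seed = seed, null_model = null_model
    ),
    class = "omiclust_fit"
  )
}

#' @export
print.omiclust_fit <- function(x, ...) {
  cat("<omiclust_fit> K = ", x$K, " (", x$n_factors, " latent factor(s)), n = ",
      x$n, "\n", sep = "")
  cat("  penalties: ", paste(sprintf("%s = %.3g", names(x$penalties), x$penalties),
                             collapse = ", "), "\n", sep = "")
  sel <- selected_features(x)
  cnt <- attr(sel, "counts")
  cat("  selected features: ",
      paste(sprintf("%s = %d", names(cnt), cnt), collapse = ", "), "\n", sep = "")
  cat("  converged: ", x$converged, " after ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

#' Assign samples to clusters in the latent subspace
#'
#' K-means on the posterior means of the latent factors, with multiple
#' restarts under a fixed seed; clusters are renumbered by first occurrence
#' so the labelling is deterministic.
#'
#' @param posterior_mean `(K-1) x n` matrix of posterior factor means.
#' @param K Number of clusters.
#' @param seed Seed controlling the K-means restarts.
#' @param nstart Number of restarts (best within-cluster sum of squares kept).
#' @return Integer vector of `n` labels in `1..K`.
#' @export
assign_clusters <- function(posterior_mean, K, seed = 1L, nstart = 20) {
  pm <- as.matrix(posterior_mean)
  n <- ncol(pm)
  if (K >= 2 && nrow(unique(t(pm))) < K) {
    abort("Fewer distinct sample points than clusters in the latent subspace.")
  }
  km <- withr::with_seed(as.integer(seed), {
    tryCatch(kmeans(t(pm), centers = K, nstart = nstart, iter.max = 100),
             error = function(e) kmeans(t(pm), centers = K, nstart = nstart * 2,
                                        iter.max = 100, algorithm = "Lloyd"))
  })
  relabel_by_first_occurrence(km$cluster)
}

#' Predict cluster membership for new samples
#'
#' Applies the training standardization, projects the new samples to their
#' posterior factor means through the fitted loadings, and assigns each to
#' the nearest fitted cluster centroid.
#'
#' @param object A fitted `omiclust_fit`.
#' @param newdata An `omics_dataset` (or list of matrices) with the same
#'   data types and features as the training data.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cluster`, and the latent coordinates
#'   (`factor_1`, ...).
#' @export
predict.omiclust_fit <- function(object, newdata, ...) {
  dataset <- as_omics_dataset(newdata)
  if (!identical(dataset$types$type, object$types)) {
    abort("`newdata` must contain the same data types as the training data.")
  }
  std <- apply_standardization(dataset, object$standardization)
  stk <- stack_dataset(std)
  B <- do.call(rbind, unname(object$loadings))
  psi <- unlist(unname(object$psi), use.names = FALSE)
  if (!identical(rownames(stk$X), rownames(B))) {
    stk$X <- stk$X[rownames(B), , drop = FALSE]
  }
  es <- em_e_step(B, psi, stk$X)
  d2 <- vapply(seq_len(ncol(object$centers)), function(k) {
    colSums((es$mean - object$centers[, k])^2)
  }, numeric(ncol(stk$X)))
  cl <- max.col(-matrix(d2, ncol = ncol(object$centers)))
  coords <- t(es$mean)
  colnames(coords) <- paste0("factor_", seq_len(object$n_factors))
  out <- tibble(sample_id = dataset$sample_ids, cluster = as.integer(cl))
  dplyr::bind_cols(out, as_tibble(coords))
}

#' Features selected by the sparse fit
#'
#' A feature is selected when at least one entry of its loading row exceeds
#' `tol` in absolute value; with exact zeros from soft-thresholding the
#' default `tol = 0` reports exactly the surviving rows.
#'
#' @param model A fitted `omiclust_fit`.
#' @param tol Non-negative magnitude below which a loading counts as zero.
#' @return A tibble with `type`, `index`, `feature` and `max_abs_loading`,
#'   with a `counts` attribute (named per-type selected counts).
#' @export
selected_features <- function(model, tol = 0) {
  stopifnot(inherits(model, "omiclust_fit"))
  check_scalar_number(tol, "tol", min = 0)
  per_type <- imap(model$loadings, function(B, tp) {
    keep <- unname(which(apply(abs(B) > tol, 1, any)))
    tibble(type = tp, index = keep, feature = rownames(B)[keep],
           max_abs_loading = apply(abs(B[keep, , drop = FALSE]), 1,
                                   max)[seq_along(keep)])
  })
  out <- list_rbind(unname(per_type))
  counts <- vapply(per_type, nrow, integer(1))
  attr(out, "counts") <- counts
  out
}

#' Cluster assignments of a fit as a tidy table
#' @param model A fitted `omiclust_fit`.
#' @return A tibble with `sample_id` and `cluster`.
#' @export
cluster_assignments <- function(model) {
  tibble(sample_id = names(model$labels), cluster = as.integer(model$labels))
}

#' @export
tidy.omiclust_fit <- function(x, ...) {
  list_rbind(unname(imap(x$loadings, function(B, tp) {
    tibble(type = tp,
           feature = rep(rownames(B), ncol(B)),
           factor = rep(seq_len(ncol(B)), each = nrow(B)),
           loading = as.vector(B))
  })))
}

#' @export
glance.omiclust_fit <- function(x, ...) {
  cnt <- attr(selected_features(x), "counts")
  tibble(K = x$K, n_factors = x$n_factors, n_samples = x$n,
         n_selected = sum(cnt), converged = x$converged, n_iter = x$n_iter,
         loglik = if (length(x$loglik_trace)) x$loglik_trace[length(x$loglik_trace)]
                  else NA_real_)
}

#' Plot samples in the fitted latent subspace
#'
#' Scatter plot of the first two latent factors (or a one-dimensional strip
#' when `K = 2`), coloured by cluster.
#'
#' @param object A fitted `omiclust_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omiclust_fit <- function(object, ...) {
  pm <- object$posterior_mean
  df <- tibble(
    sample_id = colnames(pm),
    factor_1 = pm[1, ],
    factor_2 = if (nrow(pm) >= 2) pm[2, ] else 0,
    cluster = factor(object$labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$factor_1, .data$factor_2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Latent factor 1",
                  y = if (nrow(pm) >= 2) "Latent factor 2" else "",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}
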