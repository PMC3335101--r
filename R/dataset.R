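#' Assemble a multi-omics dataset
#'
#' Bundles two or more feature-by-sample numeric matrices measured on the
#' same samples (for example copy number, DNA methylation beta values and
#' mRNA expression) into a single validated container.  All matrices must
#' have the same columns in the same order; columns are samples, rows are
#' genomic features.
#'
#' @param ... Named numeric matrices, features in rows, samples in columns.
#'   Alternatively a single named list of such matrices.
#' @param sample_ids Optional character vector of sample identifiers; when
#'   the matrices lack column names these are applied to every matrix.
#'
#' @return An object of class `omics_dataset`: a list with elements
#'   `matrices` (named list of matrices), `sample_ids`, `feature_ids`
#'   (per-type rownames) and `types` (a tibble with `type` and `p`).
#' @examples
#' x <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' y <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("m", 1:3), paste0("s", 1:5)))
#' omics_dataset(expr = x, meth = y)
#' @export
omics_dataset <- function(..., sample_ids = NULL) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is.matrix(mats[[1]])) {
    mats <- mats[[1]]
  }
  if (length(mats) == 0L) abort("At least one data matrix is required.")
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- paste0("type", seq_along(mats))
  }
  mats <- lapply(mats, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- unique(vapply(mats, ncol, integer(1)))
  if (length(n) != 1L) {
    abort("All data types must have the same number of samples (columns).")
  }
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != n) abort("`sample_ids` has the wrong length.")
    mats <- lapply(mats, function(m) { colnames(m) <- sample_ids; m })
  }
  ids <- lapply(mats, colnames)
  if (any(vapply(ids, is.null, logical(1)))) {
    sample_ids <- ids[[which(!vapply(ids, is.null, logical(1)))[1]]] %||%
      paste0("sample", seq_len(n))
    mats <- lapply(mats, function(m) { colnames(m) <- sample_ids; m })
  } else {
    sample_ids <- ids[[1]]
    mismatch <- !vapply(ids, identical, logical(1), y = sample_ids)
    if (any(mismatch)) {
      abort(paste0("Sample identifiers differ across data types (",
                   paste(names(mats)[mismatch], collapse = ", "),
                   "); use read_omics() to intersect and align them."))
    }
  }
  mats <- imap(mats, function(m, nm) {
    if (is.null(rownames(m))) rownames(m) <- paste0(nm, "_f", seq_len(nrow(m)))
    m
  })
  bad <- vapply(mats, function(m) any(!is.finite(m)), logical(1))
  if (any(bad)) {
    abort(paste0("Non-finite values in data type(s): ",
                 paste(names(mats)[bad], collapse = ", "),
                 ". Impute or drop incomplete features before assembly."))
  }
  structure(
    list(
      matrices = mats,
      sample_ids = sample_ids,
      feature_ids = lapply(mats, rownames),
      types = tibble(type = names(mats), p = unname(vapply(mats, nrow, integer(1))))
    ),
    class = "omics_dataset"
  )
}

#' Coerce to an omics_dataset
#'
#' @param x An `omics_dataset`, a named list of matrices, or a single matrix.
#' @return An `omics_dataset`.
#' @export
as_omics_dataset <- function(x) {
  if (inherits(x, "omics_dataset")) return(x)
  if (is.matrix(x)) return(omics_dataset(type1 = x))
  if (is.list(x)) return(omics_dataset(x))
  abort("Cannot coerce to an omics_dataset.")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("<omics_dataset> ", length(x$matrices), " data type(s), ",
      length(x$sample_ids), " samples\n", sep = "")
  for (i in seq_len(nrow(x$types))) {
    cat("  ", x$types$type[i], ": ", x$types$p[i], " features\n", sep = "")
  }
  std <- attr(x, "standardization")
  if (!is.null(std)) cat("  standardized: ", std$mode, "\n", sep = "")
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An `omics_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(as_omics_dataset(dataset)$sample_ids)

#' Subset the samples of a dataset
#'
#' @param dataset An `omics_dataset`.
#' @param idx Integer, logical or character index into the samples.
#' @return An `omics_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  dataset <- as_omics_dataset(dataset)
  out <- omics_dataset(lapply(dataset$matrices, function(m) m[, idx, drop = FALSE]))
  attr(out, "standardization") <- attr(dataset, "standardization")
  out
}

#' Restrict a dataset to a subset of its data types
#' @param dataset An `omics_dataset`.
#' @param types Character vector of type names (or integer positions).
#' @return An `omics_dataset` with only the requested types.
#' @export
subset_types <- function(dataset, types) {
  dataset <- as_omics_dataset(dataset)
  omics_dataset(dataset$matrices[types])
}

#' Standardize each feature of every data type
#'
#' The latent-variable model assumes mean-zero errors, so features are
#' centred (and usually scaled) per data type before fitting.  The applied
#' per-feature centre and scale are recorded in the returned object so that
#' held-out samples can be transformed identically.
#'
#' @param dataset An `omics_dataset` (or anything [as_omics_dataset()] accepts).
#' @param mode `"zscore"` (centre and scale to unit sample SD, the default),
#'   `"center"`, or `"none"`.
#' @param zero_variance What to do with zero-variance features under
#'   `"zscore"`: `"drop"` them with a warning, or `"error"`.
#'
#' @return An `omics_dataset` with a `standardization` attribute recording
#'   `mode` and the per-type `center`/`scale` vectors used.
#' @examples
#' d <- omics_dataset(a = matrix(1:6, 2, 3))
#' standardize(d, "center")
#' @export
standardize <- function(dataset, mode = c("zscore", "center", "none"),
                        zero_variance = c("drop", "error")) {
  dataset <- as_omics_dataset(dataset)
  mode <- match.arg(mode)
  zero_variance <- match.arg(zero_variance)
  if (mode == "none") {
    attr(dataset, "standardization") <- list(mode = "none")
    return(dataset)
  }
  centers <- list(); scales <- list()
  mats <- imap(dataset$matrices, function(m, nm) {
    ctr <- rowMeans(m)
    m <- m - ctr
    scl <- rep(1, nrow(m))
    if (mode == "zscore") {
      scl <- apply(m, 1, sd)
      zv <- scl <= .Machine$double.eps * 10
      if (any(zv)) {
        if (zero_variance == "error") {
          abort(sprintf("%d zero-variance feature(s) in type '%s' under zscore.",
                        sum(zv), nm))
        }
        warn(sprintf("Dropping %d zero-variance feature(s) from type '%s'.",
                     sum(zv), nm))
        m <- m[!zv, , drop = FALSE]; ctr <- ctr[!zv]; scl <- scl[!zv]
      }
      m <- m / scl
    }
    centers[[nm]] <<- ctr
    scales[[nm]] <<- scl
    m
  })
  out <- omics_dataset(mats)
  attr(out, "standardization") <- list(mode = mode, center = centers, scale = scales)
  out
}

# apply a recorded standardization to new data with the same features
apply_standardization <- function(dataset, std) {
  dataset <- as_omics_dataset(dataset)
  if (is.null(std) || std$mode == "none") return(dataset)
  mats <- imap(dataset$matrices, function(m, nm) {
    keep <- names(std$center[[nm]])
    m <- m[keep, , drop = FALSE]
    (m - std$center[[nm]]) / std$scale[[nm]]
  })
  out <- omics_dataset(mats)
  attr(out, "standardization") <- std
  out
}

# stack all data types into one p_total x n matrix, with a type index
stack_dataset <- function(dataset) {
  mats <- dataset$matrices
  X <- do.call(rbind, unname(mats))
  type_index <- rep(names(mats), times = vapply(mats, nrow, integer(1)))
  list(X = X, type_index = type_index, types = names(mats))
}
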