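# Reading delimited matrices and writing run artifacts.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

read_matrix_file <- function(path, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read delimited matrices into a multi-omics dataset
#'
#' Each file holds one data type: features as rows, samples as columns,
#' first row sample identifiers, first column feature identifiers.  The
#' delimiter (tab or comma) is sniffed per file unless given.  Samples are
#' intersected across files and reordered to a common order; an error is
#' raised when no samples are shared.
#'
#' @param paths Named character vector of file paths (names become the data
#'   type names; basenames are used otherwise).
#' @param delim Optional explicit delimiter applied to every file.
#' @return An [omics_dataset()].
#' @export
read_omics <- function(paths, delim = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  }
  mats <- lapply(paths, read_matrix_file, delim = delim)
  ids <- Reduce(intersect, lapply(mats, colnames))
  if (length(ids) == 0) {
    abort(paste0(
      "No samples shared across input files. Per-file samples: ",
      paste(vapply(mats, function(m) paste0(head(colnames(m), 3), collapse = ","),
                   character(1)), collapse = " | ")))
  }
  dropped <- unlist(lapply(mats, function(m) setdiff(colnames(m), ids)))
  if (length(dropped)) {
    warn(sprintf("Dropping %d sample(s) absent from some data types: %s",
                 length(dropped), paste(head(unique(dropped), 5), collapse = ", ")))
  }
  omics_dataset(lapply(mats, function(m) m[, ids, drop = FALSE]))
}

write_matrix_tsv <- function(m, path) {
  df <- dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write cluster labels as a two-column TSV
#' @param labels Named integer vector or the tibble from
#'   [cluster_assignments()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- if (is.data.frame(labels)) as_tibble(labels)
        else tibble(sample_id = names(labels), cluster = as.integer(labels))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Serialize a fitted model to a JSON container
#'
#' Writes every component of an `omiclust_fit` (loadings, residual
#' variances, posterior moments, labels, penalties, standardization,
#' convergence trace) as structured JSON so a fit can be archived and
#' reloaded without binary files.
#'
#' @param fit An `omiclust_fit`.
#' @param path Output `.json` file.
#' @return The path, invisibly.
#' @export
write_omiclust_model <- function(fit, path) {
  payload <- list(
    container = "omiclust_fit", version = 1L,
    K = fit$K, n_factors = fit$n_factors, n = fit$n,
    types = fit$types, penalties = as.list(fit$penalties),
    weighted = fit$weighted,
    loadings = lapply(fit$loadings, function(B)
      list(features = rownames(B), values = unname(B))),
    psi = lapply(fit$psi, function(v) list(features = names(v), values = unname(v))),
    posterior_mean = unname(fit$posterior_mean),
    posterior_cov = unname(fit$posterior_cov),
    centers = unname(fit$centers),
    labels = list(sample_id = names(fit$labels), cluster = unname(fit$labels)),
    loglik_trace = fit$loglik_trace, converged = fit$converged,
    n_iter = fit$n_iter, seed = fit$seed,
    standardization = fit$standardization
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload a fitted model written by [write_omiclust_model()]
#' @param path A model `.json` file.
#' @return An `omiclust_fit`.
#' @export
read_omiclust_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$container, "omiclust_fit")) abort("Not an omiclust model file.")
  loadings <- lapply(j$loadings, function(l) {
    B <- as.matrix(l$values); rownames(B) <- l$features; B
  })
  psi <- lapply(j$psi, function(l) setNames(as.numeric(l$values), l$features))
  std <- j$standardization
  if (!is.null(std$center)) {
    std$center <- map2(std$center, loadings[names(std$center)],
                       function(v, B) setNames(as.numeric(v), rownames(B)))
    std$scale <- map2(std$scale, loadings[names(std$scale)],
                      function(v, B) setNames(as.numeric(v), rownames(B)))
  }
  structure(
    list(K = j$K, n_factors = j$n_factors, n = j$n,
         loadings = loadings, psi = psi,
         penalties = unlist(j$penalties), weighted = j$weighted,
         posterior_mean = `colnames<-`(as.matrix(j$posterior_mean),
                                       j$labels$sample_id),
         posterior_cov = as.matrix(j$posterior_cov),
         labels = setNames(as.integer(j$labels$cluster), j$labels$sample_id),
         centers = as.matrix(j$centers),
         loglik_trace = j$loglik_trace, converged = j$converged,
         n_iter = j$n_iter, standardization = std,
         types = j$types, seed = j$seed,
         null_model = all(vapply(loadings, function(B) all(B == 0), logical(1)))),
    class = "omiclust_fit")
}

#' Write and read flat key=value run configurations
#'
#' A run configuration is a named list of scalar values; the file form is
#' one `key=value` line per entry.  Reading back the written file restores
#' the configuration losslessly (values as character; consumers coerce).
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @return `write_run_config()` the path; `read_run_config()` a named list
#'   of character scalars.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  lines <- vapply(names(config), function(k)
    paste0(k, "=", as.character(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}
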