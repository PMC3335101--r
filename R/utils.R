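# internal helpers shared across modules

# all permutations of seq_len(k); k is always small (<= 7) in this package
all_permutations <- function(k) {
  stopifnot(k >= 1, k <= 7)
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(k), i)[p])))
  }
  out
}

# relabel integer cluster labels so clusters are numbered by first appearance;
# keeps seeded k-means output stable across platforms
relabel_by_first_occurrence <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

# derive a child seed; kept well below .Machine$integer.max
child_seed <- function(seed, ...) {
  off <- sum(c(...) * (7919L ^ (seq_along(c(...)) - 1L)))
  as.integer((as.double(seed) * 48271 + off) %% 2147483562) + 1L
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}

col_maxs <- function(m) {
  vapply(seq_len(ncol(m)), function(k) max(m[, k]), numeric(1))
}
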