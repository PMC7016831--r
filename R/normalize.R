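#' Counts per million
#'
#' Scales each column to counts per million of its effective library size.
#' Without normalization factors the effective size is the raw column sum;
#' with TMM factors it is `column sum * factor`.
#'
#' @param x A [count_matrix()] or a plain numeric matrix.
#' @param factors Optional [tmm_factors()] result (or a numeric vector of
#'   per-sample scaling factors).
#' @return A numeric matrix of CPM values with the same dimnames.
#' @export
cpm_matrix <- function(x, factors = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  f <- if (is.null(factors)) rep(1, ncol(counts)) else
    if (inherits(factors, "norm_factors")) factors$factor else as.numeric(factors)
  t(t(counts) / (lib * f)) * 1e6
}

#' Filter features on a CPM cutoff
#'
#' A feature is kept iff its CPM reaches `cutoff` in at least `min_samples`
#' samples — the conventional abundance filter applied before
#' differential testing (cutoff 2 by default).
#'
#' @param x A [count_matrix()].
#' @param cutoff CPM cutoff (default 2).
#' @param min_samples Number of samples that must pass (default 3).
#' @param factors Optional normalization factors forwarded to [cpm_matrix()].
#' @return A list with character vectors `kept` and `dropped`, a disjoint,
#'   exhaustive partition of the feature ids.
#' @export
filter_by_cpm <- function(x, cutoff = 2, min_samples = 3L, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (min_samples > ncol(x$counts))
    stop("min_samples exceeds the number of samples", call. = FALSE)
  cp <- cpm_matrix(x, factors)
  keep <- rowSums(cp >= cutoff) >= min_samples
  list(kept = rownames(cp)[keep], dropped = rownames(cp)[!keep])
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample, the weighted mean of
#' per-feature log2 abundance ratios (M-values) against a reference sample,
#' after trimming the most extreme `trim_m` fraction of M-values and
#' `trim_a` fraction of average abundances (A-values), weighted by inverse
#' asymptotic variance. The reference is the sample whose upper-quartile
#' relative abundance is closest to the mean across samples. Factors are
#' rescaled so their geometric mean is 1; effective library size =
#' raw library size x factor.
#'
#' @param x A [count_matrix()] or numeric matrix (>= 2 columns, positive sums).
#' @param trim_m Fraction of M-values trimmed from each tail (default 0.3).
#' @param trim_a Fraction of A-values trimmed from each tail (default 0.05).
#' @return An object of class `norm_factors`: data.frame with `sample`,
#'   `lib_size` and `factor`.
#' @export
tmm_factors <- function(x, trim_m = 0.3, trim_a = 0.05) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("non-positive library size in sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  rel <- t(t(counts) / lib)
  uq <- apply(rel, 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a),
    numeric(1))
  f <- f / exp(mean(log(f)))
  structure(data.frame(sample = colnames(counts) %||% as.character(seq_along(f)),
                       lib_size = as.numeric(lib), factor = f,
                       stringsAsFactors = FALSE),
            class = c("norm_factors", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One sample against the reference: doubly trimmed, precision-weighted mean
# of M-values (log2 ratio of relative abundances).
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  if (!any(fin))
    stop("no features with positive counts in both the sample and the TMM reference",
         call. = FALSE)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Effective library sizes
#' @param x A [count_matrix()].
#' @param factors Optional `norm_factors`.
#' @return Numeric vector of effective library sizes (size x factor).
#' @export
effective_lib_sizes <- function(x, factors = NULL) {
  lib <- colSums(x$counts)
  if (is.null(factors)) return(lib)
  lib * factors$factor
}
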