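#' Estimate a common negative-binomial dispersion
#'
#' Estimates a single dispersion phi (variance = mu + phi mu^2) shared by
#' all features, by maximizing the conditional log-likelihood of the
#' within-group counts given their group totals, after scaling every sample
#' to a common effective library size (the geometric mean) and rounding.
#' For independent NB replicates with a common mean, the within-group
#' likelihood conditional on the group sum does not involve the mean, so
#' the profile over phi is free of the per-feature nuisance parameters.
#' A method-of-moments estimator is available as a fallback and for
#' cross-checking.
#'
#' @param x A [count_matrix()].
#' @param groups Factor or vector assigning samples to groups; at least one
#'   group must contain >= 2 replicates.
#' @param factors Optional [tmm_factors()] result.
#' @param method `"qcml"` (conditional maximum likelihood, default) or
#'   `"moments"`.
#' @return A single dispersion estimate phi >= 0.
#' @export
estimate_common_dispersion <- function(x, groups, factors = NULL,
                                       method = c("qcml", "moments")) {
  stopifnot(inherits(x, "count_matrix"))
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (length(groups) != ncol(x$counts))
    stop("groups must have one entry per sample", call. = FALSE)
  if (max(table(groups)) < 2L)
    stop("no group has replication; supply a dispersion explicitly", call. = FALSE)
  pseudo <- equalize_libraries(x$counts, factors)
  if (method == "moments") return(moments_dispersion(pseudo, groups))
  ll <- function(log_phi) cond_loglik(pseudo, groups, exp(log_phi))
  opt <- stats::optimize(ll, interval = log(c(1e-6, 20)), maximum = TRUE)
  phi <- exp(opt$maximum)
  # boundary solution: the likelihood keeps increasing toward phi -> 0
  if (phi < 5e-6 || ll(log(1e-6)) >= opt$objective) return(0)
  phi
}

# Scale counts to the geometric mean of effective library sizes and round.
equalize_libraries <- function(counts, factors = NULL) {
  lib <- colSums(counts)
  eff <- if (is.null(factors)) lib else lib * factors$factor
  common <- exp(mean(log(eff)))
  round(t(t(counts) * (common / eff)))
}

# Conditional log-likelihood of within-group counts given group totals,
# summed over features and groups, for NB(mean mu, size r = 1/phi).
cond_loglik <- function(pseudo, groups, phi) {
  r <- 1 / phi
  total <- 0
  for (g in levels(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    total <- total + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                           lgamma(n * r) - lgamma(z + n * r))
  }
  total
}

moments_dispersion <- function(pseudo, groups, trim = 0.05) {
  num <- 0; den <- 0
  for (g in levels(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    if (ncol(y) < 2L) next
    m <- rowMeans(y)
    v <- apply(y, 1L, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  max(0, num / den)
}

#' Conditional negative-binomial exact test
#'
#' Pairwise exact test for a two-group contrast on NB counts, conditioning
#' on the per-feature total. Counts are first scaled to a common effective
#' library size; within each group they are summed. Under the null the
#' group sums are NB with sizes `n_A/phi` and `n_B/phi` and means
#' proportional to group size, and the two-sided p-value is the total
#' conditional probability of all splits of the observed total that are no
#' more likely than the observed one. With `phi = 0` this reduces to the
#' exact binomial test of the group-A sum against `n_A / (n_A + n_B)`.
#'
#' The log2 fold change is reported for group B relative to group A
#' (convention: group A = drug-sensitive, group B = MDR, so positive logFC
#' means higher in MDR), moderated by a prior count.
#'
#' @param x A [count_matrix()].
#' @param group_a,group_b Character vectors of sample labels for the two
#'   groups (A = baseline/sensitive, B = MDR).
#' @param phi NB dispersion (e.g. from [estimate_common_dispersion()]).
#' @param factors Optional [tmm_factors()] result.
#' @param keep Optional character vector of feature ids that passed the
#'   abundance filter (see [filter_by_cpm()]); other features are reported
#'   untested with `NA` p-values.
#' @param prior_count Prior count per group average for the logFC (default 0.5).
#' @return A data.frame of class `de_result` with columns `feature_id`,
#'   `logfc`, `p_value`, `adjusted_p`, `mean_log2_cpm`, `tested`.
#'   Adjusted p-values are Benjamini-Hochberg over the tested features.
#' @export
nb_exact_test <- function(x, group_a, group_b, phi, factors = NULL,
                          keep = NULL, prior_count = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  lab <- x$samples$label
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  miss <- setdiff(c(group_a, group_b), lab)
  if (length(miss)) stop("unknown sample label(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  pseudo <- equalize_libraries(x$counts, factors)
  ja <- match(group_a, colnames(pseudo)); jb <- match(group_b, colnames(pseudo))
  na <- length(ja); nb_ <- length(jb)
  ya <- rowSums(pseudo[, ja, drop = FALSE])
  yb <- rowSums(pseudo[, jb, drop = FALSE])
  fid <- rownames(pseudo)
  tested <- if (is.null(keep)) rep(TRUE, length(fid)) else fid %in% keep

  pv <- rep(NA_real_, length(fid))
  idx <- which(tested)
  pv[idx] <- vapply(idx, function(i)
    exact_nb_pvalue(ya[i], ya[i] + yb[i], na, nb_, phi), numeric(1))
  lfc <- log2((yb / nb_ + prior_count) / (ya / na + prior_count))
  lfc[!tested] <- NA_real_
  cp <- cpm_matrix(x, factors)
  res <- data.frame(feature_id = fid,
                    logfc = lfc,
                    p_value = pv,
                    adjusted_p = NA_real_,
                    mean_log2_cpm = log2(rowMeans(cp) + 0.25),
                    tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$adjusted_p[tested] <- bh_adjust(res$p_value[tested])
  class(res) <- c("de_result", "data.frame")
  attr(res, "phi") <- phi
  res
}

# Two-sided conditional exact p-value for the split (ya, t - ya) of total t
# between groups of na and nb libraries at dispersion phi.
exact_nb_pvalue <- function(ya, t, na, nb_, phi) {
  if (t == 0) return(1)
  a <- 0:t
  if (phi > 0) {
    lp <- stats::dnbinom(a, size = na / phi, mu = t * na / (na + nb_), log = TRUE) +
      stats::dnbinom(t - a, size = nb_ / phi, mu = t * nb_ / (na + nb_), log = TRUE)
  } else {
    lp <- stats::dbinom(a, t, na / (na + nb_), log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  obs <- p[ya + 1L]
  sum(p[p <= obs * (1 + 1e-7)]) / sum(p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' @export
print.de_result <- function(x, n = 10L, ...) {
  cat(sprintf("de_result: %d features (%d tested), phi = %g\n",
              nrow(x), sum(x$tested), attr(x, "phi")))
  ord <- order(x$p_value)
  print.data.frame(utils::head(x[ord, ], n))
  invisible(x)
}

#' Run the sensitive-vs-MDR exact test for one model and compartment
#'
#' Convenience wrapper chaining the standard stages: subset to the
#' requested model/compartment, TMM factors, CPM filter, common dispersion
#' and the exact test, with drug-sensitive samples as baseline.
#'
#' @param x The full study [count_matrix()].
#' @param model `"NSCLC"` or `"CML"`.
#' @param compartment `"cell"` or `"EV"`.
#' @param config A [pipeline_config()].
#' @param phi Optional dispersion override; estimated when `NULL`.
#' @return A `de_result` (see [nb_exact_test()]).
#' @export
de_contrast <- function(x, model, compartment, config = pipeline_config(),
                        phi = NULL) {
  sub <- subset_samples(x, model = model, compartment = compartment)
  f <- tmm_factors(sub)
  flt <- filter_by_cpm(sub, cutoff = config$cpm_cutoff,
                       min_samples = config$min_samples_passing, factors = f)
  grp <- sub$samples$phenotype
  if (is.null(phi))
    phi <- estimate_common_dispersion(sub, grp, factors = f)
  res <- nb_exact_test(sub,
                       group_a = sub$samples$label[grp == "sensitive"],
                       group_b = sub$samples$label[grp == "MDR"],
                       phi = phi, factors = f, keep = flt$kept,
                       prior_count = config$logfc_prior_count)
  attr(res, "contrast") <- paste(model, compartment, sep = "_")
  res
}
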