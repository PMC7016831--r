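#' Pipeline configuration
#'
#' Collects the tunable parameters shared by the analysis stages. Defaults
#' follow the conventions of count-based small-RNA differential analysis:
#' features must reach 2 counts per million in at least one full replicate
#' group to be tested, significance is called at 0.05, and the
#' noise-threshold grid for the selectivity regression spans 0 to 10 on the
#' log2 RPM scale in steps of 0.1.
#'
#' @param cpm_cutoff Minimum counts-per-million for the abundance filter.
#' @param min_samples_passing Number of samples that must reach `cpm_cutoff`
#'   (default 3, one full replicate group).
#' @param alpha Significance level for differential-expression calls.
#' @param use_adjusted Logical; call significance on Benjamini-Hochberg
#'   adjusted p-values instead of raw p-values.
#' @param grid_lo,grid_hi,grid_step Noise-threshold grid (log2 RPM scale).
#' @param logfc_prior_count Prior count per group average used to stabilise
#'   log fold changes at zero counts.
#' @param r2_ceiling R-squared ceiling below which EV packaging is reported
#'   as selective rather than proportional.
#' @param threshold_axes Which axes the noise threshold filters:
#'   `"both"` (default), `"x"` or `"y"`.
#' @param cluster_distance,cluster_linkage Feature-clustering defaults.
#' @param mds_top_k Number of top features for the leading-logFC distance.
#' @param rng_seed Seed used by stages that draw random numbers.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cpm_cutoff = 2, min_samples_passing = 3L,
                            alpha = 0.05, use_adjusted = FALSE,
                            grid_lo = 0, grid_hi = 10, grid_step = 0.1,
                            logfc_prior_count = 0.5, r2_ceiling = 0.8,
                            threshold_axes = c("both", "x", "y"),
                            cluster_distance = c("correlation", "euclidean"),
                            cluster_linkage = "average",
                            mds_top_k = 500L, rng_seed = 1L) {
  threshold_axes <- match.arg(threshold_axes)
  cluster_distance <- match.arg(cluster_distance)
  cfg <- list(cpm_cutoff = cpm_cutoff,
              min_samples_passing = as.integer(min_samples_passing),
              alpha = alpha, use_adjusted = isTRUE(use_adjusted),
              grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
              logfc_prior_count = logfc_prior_count, r2_ceiling = r2_ceiling,
              threshold_axes = threshold_axes,
              cluster_distance = cluster_distance,
              cluster_linkage = cluster_linkage,
              mds_top_k = as.integer(mds_top_k),
              rng_seed = as.integer(rng_seed))
  if (!(cfg$grid_lo < cfg$grid_hi)) stop("grid_lo must be < grid_hi", call. = FALSE)
  if (cfg$grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$cpm_cutoff < 0) stop("cpm_cutoff must be >= 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields absent from the file keep their [pipeline_config()] defaults;
#' unknown fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configuration requires the 'yaml' package", call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}
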