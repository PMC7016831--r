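#' Simulation configuration for paired cell/EV small-RNA count data
#'
#' Describes a synthetic study with the structure of a paired
#' drug-sensitive/MDR EV-sequencing experiment: 2 tumor models (NSCLC, CML)
#' x 2 compartments (cell, EV) x 2 phenotypes (sensitive, MDR) x 3
#' replicates. Per model, features receive log-normal baseline abundances;
#' a fraction carries an MDR effect (log2 fold change), partly shared in
#' sign across the two models; EV abundance is the donor-cell abundance
#' times a per-feature packaging factor and a logistic detection indicator,
#' so every EV species also exists in cells. Counts are negative binomial
#' with variance mu + phi * mu^2.
#'
#' Baseline abundances are rescaled within each biotype so that the expected
#' read composition of the sensitive cell samples matches
#' `biotype_proportions` exactly; recovery of those proportions by
#' composition profiling is then limited only by sampling noise.
#'
#' @param n_features Number of features.
#' @param biotype_proportions Named numeric vector of expected read
#'   fractions per biotype; must sum to 1.
#' @param log2_mean_baseline Length-2 vector `(mu0, sigma0)`: per-model
#'   baseline log2 abundances are drawn Normal(mu0, sigma0).
#' @param nb_dispersion Negative-binomial dispersion phi >= 0 (0 = Poisson).
#' @param library_size_range Length-2 integer vector; per-sample library
#'   sizes are drawn uniformly from this range.
#' @param de_fraction Fraction of features with an MDR effect.
#' @param de_logfc_location,de_logfc_scale Location and scale of the
#'   half-normal draw for |log2 fold change| of affected features.
#' @param shared_de_fraction Fraction of affected features whose effect has
#'   the same sign in both tumor models (magnitudes drawn independently);
#'   the remainder are affected in one model only.
#' @param packaging_mode `"proportional"` (all packaging factors 1) or
#'   `"selective"`.
#' @param selective_fraction In selective mode, the fraction of features
#'   whose packaging factor is drawn log-normal.
#' @param packaging_log_sd Standard deviation, on the natural-log scale, of
#'   the log-normal packaging factors.
#' @param dropout_midpoint,dropout_slope Logistic EV-detection parameters on
#'   the log2 RPM scale: detection probability =
#'   `plogis((log2_rpm - midpoint) * slope)`. `dropout_midpoint = -Inf`
#'   disables dropout.
#' @param forced_effects Optional data.frame planting exact effects on
#'   specific features, overriding the random draws. Must have a `feature`
#'   column (integer indices); optional columns: `base_log2` (baseline
#'   log2 RPM in both models), `logfc_NSCLC`/`logfc_CML` (cell MDR
#'   effects), `ev_logfc_NSCLC`/`ev_logfc_CML` (MDR-dependent packaging
#'   shifts applied to EV abundance only, emulating EV-specific
#'   regulation), `detect_NSCLC`/`detect_CML` (logical EV-detection flags).
#' @param rng_seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_features = 5000L,
                       biotype_proportions = c(pseudogene = 0.15, miRNA = 0.03,
                                               protein_coding = 0.55, rRNA = 0.05,
                                               tRNA = 0.07, snRNA = 0.05, other = 0.10),
                       log2_mean_baseline = c(5, 2),
                       nb_dispersion = 0.1,
                       library_size_range = c(1e6, 5e6),
                       de_fraction = 0.1,
                       de_logfc_location = 2, de_logfc_scale = 0.5,
                       shared_de_fraction = 0.3,
                       packaging_mode = c("selective", "proportional"),
                       selective_fraction = 0.3,
                       packaging_log_sd = 1.5,
                       dropout_midpoint = 2, dropout_slope = 1,
                       forced_effects = NULL,
                       rng_seed = 1L) {
  packaging_mode <- match.arg(packaging_mode)
  cfg <- as.list(environment())
  cfg$n_features <- as.integer(n_features)
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_features < 1L) stop("n_features must be >= 1", call. = FALSE)
  p <- cfg$biotype_proportions
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("biotype_proportions must be named", call. = FALSE)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("biotype_proportions must lie in [0,1] and sum to 1", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  for (fr in c("de_fraction", "shared_de_fraction", "selective_fraction"))
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1)
      stop(fr, " must lie in [0, 1]", call. = FALSE)
  if (cfg$packaging_log_sd < 0) stop("packaging_log_sd must be >= 0", call. = FALSE)
  if (length(cfg$library_size_range) != 2L ||
      cfg$library_size_range[1L] > cfg$library_size_range[2L] ||
      cfg$library_size_range[1L] <= 0)
    stop("library_size_range must be positive and non-decreasing", call. = FALSE)
  if (length(cfg$log2_mean_baseline) != 2L || cfg$log2_mean_baseline[2L] < 0)
    stop("log2_mean_baseline must be (mu0, sigma0) with sigma0 >= 0", call. = FALSE)
  f <- cfg$forced_effects
  if (!is.null(f)) {
    if (!"feature" %in% names(f))
      stop("forced_effects needs a 'feature' column", call. = FALSE)
    if (any(f$feature < 1L | f$feature > cfg$n_features))
      stop("forced_effects refers to feature indices outside 1..n_features",
           call. = FALSE)
    known <- c("feature", "base_log2", paste0("logfc_", MODEL_LEVELS),
               paste0("ev_logfc_", MODEL_LEVELS), paste0("detect_", MODEL_LEVELS))
    bad <- setdiff(names(f), known)
    if (length(bad))
      stop("unknown forced_effects column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  cfg
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Apply the EV packaging and dropout model to cell abundances
#'
#' In proportional mode every feature keeps its donor-cell abundance
#' (packaging factor 1); in selective mode a configurable fraction of
#' features receives a log-normal packaging factor. Independently, each
#' feature is detected in the EV fraction with probability
#' `plogis((log2(abundance) - dropout_midpoint) * dropout_slope)`;
#' undetected features get EV abundance 0. Consumes the current RNG stream.
#'
#' @param cell_abundance Non-negative abundances, one per feature, on the
#'   scale on which `dropout_midpoint` is expressed (log2 of this value is
#'   compared with the midpoint).
#' @param config A [sim_config()].
#' @return A list with `ev_abundance`, `factors` and `detected`.
#' @export
apply_packaging <- function(cell_abundance, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(cell_abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  n <- length(cell_abundance)
  factors <- rep(1, n)
  if (config$packaging_mode == "selective" && config$selective_fraction > 0) {
    sel <- stats::runif(n) < config$selective_fraction
    factors[sel] <- exp(stats::rnorm(sum(sel), 0, config$packaging_log_sd))
  }
  if (is.infinite(config$dropout_midpoint) && config$dropout_midpoint < 0) {
    p_det <- rep(1, n)
  } else {
    l2 <- ifelse(cell_abundance > 0, log2(cell_abundance), -Inf)
    p_det <- stats::plogis((l2 - config$dropout_midpoint) * config$dropout_slope)
  }
  detected <- stats::runif(n) < p_det
  list(ev_abundance = cell_abundance * factors * as.numeric(detected),
       factors = factors, detected = detected)
}

#' Generate a complete synthetic cell/EV sequencing dataset
#'
#' Draws a 24-sample dataset (2 models x 2 compartments x 2 phenotypes x 3
#' replicates) of negative-binomial counts, together with a feature
#' annotation table and the full generating truth. Counts for a sample are
#' NB with mean `library_size * abundance / sum(abundance)` and dispersion
#' `nb_dispersion`; the abundance vector is the model- and
#' phenotype-specific cell abundance, multiplied for EV samples by the
#' packaging factor and detection flag.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `counts`
#'   (a [count_matrix()]), `annotation` (feature_id, name, biotype),
#'   `truth` (per-feature baselines, log2 fold changes, packaging factors
#'   and EV-detection flags per model) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    n <- config$n_features
    fid <- sprintf("feat%05d", seq_len(n))
    props <- config$biotype_proportions
    n_per <- diff(round(cumsum(c(0, props)) * n))
    biotype <- rep(names(props), times = n_per)
    if (length(biotype) < n) biotype <- c(biotype, rep(names(props)[1L], n - length(biotype)))
    biotype <- sample(biotype[seq_len(n)])
    ann <- data.frame(feature_id = fid,
                      name = paste0(biotype, "-", seq_len(n)),
                      biotype = biotype, stringsAsFactors = FALSE)

    mu0 <- config$log2_mean_baseline[1L]; s0 <- config$log2_mean_baseline[2L]
    base <- list()
    for (m in MODEL_LEVELS) {
      a <- 2^stats::rnorm(n, mu0, s0)
      # rescale within biotype so expected sensitive-cell read shares equal props
      tot <- sum(a)
      for (b in names(props)) {
        idx <- biotype == b
        if (any(idx)) a[idx] <- a[idx] * (props[[b]] * tot / sum(a[idx]))
      }
      base[[m]] <- a * (1e6 / sum(a))  # RPM scale
    }
    forced <- config$forced_effects
    if (!is.null(forced) && "base_log2" %in% names(forced))
      for (m in MODEL_LEVELS) base[[m]][forced$feature] <- 2^forced$base_log2

    lfc <- matrix(0, n, 2, dimnames = list(fid, MODEL_LEVELS))
    n_de <- round(config$de_fraction * n)
    if (n_de > 0) {
      de_idx <- sample.int(n, n_de)
      mag <- function(k) config$de_logfc_location +
        config$de_logfc_scale * abs(stats::rnorm(k))
      shared <- de_idx[stats::runif(n_de) < config$shared_de_fraction]
      solo <- setdiff(de_idx, shared)
      sgn <- sample(c(-1, 1), length(shared), replace = TRUE)
      lfc[shared, "NSCLC"] <- sgn * mag(length(shared))
      lfc[shared, "CML"]   <- sgn * mag(length(shared))
      which_model <- sample(MODEL_LEVELS, length(solo), replace = TRUE)
      sgn_solo <- sample(c(-1, 1), length(solo), replace = TRUE)
      mag_solo <- mag(length(solo))
      for (m in MODEL_LEVELS) {
        sel <- which_model == m
        lfc[solo[sel], m] <- sgn_solo[sel] * mag_solo[sel]
      }
    }
    ev_lfc <- matrix(0, n, 2, dimnames = list(fid, MODEL_LEVELS))
    pack <- matrix(1, n, 2, dimnames = list(fid, MODEL_LEVELS))
    det <- matrix(TRUE, n, 2, dimnames = list(fid, MODEL_LEVELS))
    for (m in MODEL_LEVELS) {
      pk <- apply_packaging(base[[m]], config)
      pack[, m] <- pk$factors
      det[, m] <- pk$detected
    }
    if (!is.null(forced)) {
      for (m in MODEL_LEVELS) {
        cl <- paste0("logfc_", m)
        if (cl %in% names(forced)) lfc[forced$feature, m] <- forced[[cl]]
        cl <- paste0("ev_logfc_", m)
        if (cl %in% names(forced)) ev_lfc[forced$feature, m] <- forced[[cl]]
        cl <- paste0("detect_", m)
        if (cl %in% names(forced)) det[forced$feature, m] <- as.logical(forced[[cl]])
      }
    }

    design <- expand.grid(replicate = 1:3, phenotype = PHENOTYPE_LEVELS,
                          compartment = COMPARTMENT_LEVELS, model = MODEL_LEVELS,
                          stringsAsFactors = FALSE)[, 4:1]
    design$label <- with(design, paste(model, compartment, phenotype, replicate, sep = "_"))
    counts <- matrix(0L, n, nrow(design), dimnames = list(fid, design$label))
    lo <- config$library_size_range[1L]; hi <- config$library_size_range[2L]
    phi <- config$nb_dispersion
    for (j in seq_len(nrow(design))) {
      m <- design$model[j]
      mdr <- design$phenotype[j] == "MDR"
      ab <- base[[m]] * 2^(lfc[, m] * mdr)
      if (design$compartment[j] == "EV")
        ab <- ab * pack[, m] * det[, m] * 2^(ev_lfc[, m] * mdr)
      if (sum(ab) <= 0) stop("degenerate simulation: a sample has zero total abundance",
                             call. = FALSE)
      lib <- floor(stats::runif(1, lo, hi + 1))
      mu <- lib * ab / sum(ab)
      counts[, j] <- if (phi > 0)
        stats::rnbinom(n, size = 1 / phi, mu = mu) else stats::rpois(n, mu)
    }

    truth <- data.frame(feature_id = fid, biotype = biotype,
                        base_log2_NSCLC = log2(base$NSCLC),
                        base_log2_CML = log2(base$CML),
                        logfc_NSCLC = lfc[, "NSCLC"], logfc_CML = lfc[, "CML"],
                        ev_logfc_NSCLC = ev_lfc[, "NSCLC"],
                        ev_logfc_CML = ev_lfc[, "CML"],
                        pack_NSCLC = pack[, "NSCLC"], pack_CML = pack[, "CML"],
                        detected_NSCLC = det[, "NSCLC"], detected_CML = det[, "CML"],
                        row.names = NULL, stringsAsFactors = FALSE)
    structure(list(counts = count_matrix(counts, design[, c("label", "model",
                                                            "compartment", "phenotype",
                                                            "replicate")]),
                   annotation = ann, truth = truth, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d features, %d samples (%s packaging, phi = %g)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              x$config$packaging_mode, x$config$nb_dispersion))
  invisible(x)
}

#' Simulate a qPCR Ct table from simulation truth
#'
#' Emits per-replicate threshold-cycle values for selected features in one
#' tumor model, for the sensitive and MDR cell conditions:
#' `Ct = ct_intercept - log2(abundance) + Normal(0, ct_noise_sd)`.
#' The reference (normalizer) feature must be expression-stable in the
#' truth, i.e. carry no MDR effect in the chosen model.
#'
#' @param truth The `truth` data.frame of a [generate_dataset()] result.
#' @param features Feature ids to assay (the reference is added if absent).
#' @param reference_feature Feature id of the stable normalizer.
#' @param model `"NSCLC"` or `"CML"`.
#' @param ct_intercept Intercept in cycles (default 35).
#' @param ct_noise_sd Per-well Gaussian noise, in cycles.
#' @param n_replicates Replicates per condition.
#' @param rng_seed Integer seed.
#' @return A data.frame (`feature_id`, `condition`, `replicate`, `ct`).
#' @export
simulate_ct_table <- function(truth, features, reference_feature,
                              model = "NSCLC", ct_intercept = 35,
                              ct_noise_sd = 0.2, n_replicates = 3L,
                              rng_seed = 1L) {
  stopifnot(model %in% MODEL_LEVELS)
  features <- union(features, reference_feature)
  miss <- setdiff(features, truth$feature_id)
  if (length(miss)) stop("feature(s) absent from truth: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tr <- truth[match(features, truth$feature_id), , drop = FALSE]
  basecol <- paste0("base_log2_", model); lfccol <- paste0("logfc_", model)
  ref_lfc <- tr[[lfccol]][tr$feature_id == reference_feature]
  if (abs(ref_lfc) > 1e-12)
    stop("reference feature '", reference_feature,
         "' is not expression-stable in model ", model,
         " (planted logFC = ", format(ref_lfc), ")", call. = FALSE)
  with_seed(rng_seed, {
    out <- expand.grid(replicate = seq_len(n_replicates),
                       condition = PHENOTYPE_LEVELS,
                       feature_id = features, stringsAsFactors = FALSE)[, 3:1]
    l2 <- tr[[basecol]][match(out$feature_id, tr$feature_id)] +
      tr[[lfccol]][match(out$feature_id, tr$feature_id)] * (out$condition == "MDR")
    out$ct <- ct_intercept - l2 +
      if (ct_noise_sd > 0) stats::rnorm(nrow(out), 0, ct_noise_sd) else 0
    out
  })
}
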