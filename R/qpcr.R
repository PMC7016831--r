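#' Read a qPCR Ct table
#'
#' Tab-separated with header `feature_id`, `condition`
#' (`sensitive`/`MDR`), `replicate`, `ct`.
#'
#' @param path Path to the Ct TSV.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(tab)
}

validate_ct_table <- function(tab) {
  need <- c("feature_id", "condition", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tab$condition), PHENOTYPE_LEVELS)
  if (length(bad))
    stop("invalid condition value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$ct) | tab$ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  tab
}

#' Relative quantification by the 2^-ddCt method
#'
#' Classic comparative-Ct quantification: per condition, delta Ct is the
#' mean Ct of the target minus the mean Ct of the reference (normalizer)
#' miR; delta-delta Ct subtracts the calibrator condition's delta Ct from
#' the test condition's; the fold change of the test condition relative to
#' the calibrator is `2^-ddCt`. Per-replicate fold changes (pairing
#' replicate indices) are reported for spread. A reference whose mean Ct
#' differs by 0.5 cycles or more between conditions triggers a warning,
#' since the method assumes a stably expressed normalizer.
#'
#' @param table A Ct table (see [read_ct_table()]).
#' @param target Feature id of the assayed miR.
#' @param reference Feature id of the normalizer miR.
#' @param calibrator Condition used as baseline (default `"sensitive"`,
#'   so the fold change describes MDR relative to sensitive).
#' @return A list of class `fold_change`: `feature_id`, `delta_delta_ct`,
#'   `fold_change` (= `2^-ddCt`), `replicate_folds`.
#' @export
delta_delta_ct <- function(table, target, reference, calibrator = "sensitive") {
  table <- validate_ct_table(table)
  if (!calibrator %in% PHENOTYPE_LEVELS)
    stop("calibrator must be one of: ", paste(PHENOTYPE_LEVELS, collapse = ", "),
         call. = FALSE)
  test <- setdiff(PHENOTYPE_LEVELS, calibrator)
  ct_of <- function(feature, condition) {
    v <- table$ct[table$feature_id == feature & table$condition == condition]
    if (!length(v)) stop("no Ct values for feature '", feature,
                         "' in condition '", condition, "'", call. = FALSE)
    v
  }
  tg_cal <- ct_of(target, calibrator); tg_test <- ct_of(target, test)
  rf_cal <- ct_of(reference, calibrator); rf_test <- ct_of(reference, test)
  if (abs(mean(rf_test) - mean(rf_cal)) >= 0.5)
    warning("reference '", reference, "' differs by ",
            format(abs(mean(rf_test) - mean(rf_cal)), digits = 3),
            " cycles between conditions; 2^-ddCt assumes a stable normalizer")
  ddct <- (mean(tg_test) - mean(rf_test)) - (mean(tg_cal) - mean(rf_cal))
  nrep <- min(length(tg_cal), length(tg_test), length(rf_cal), length(rf_test))
  rep_folds <- 2^-((tg_test[seq_len(nrep)] - rf_test[seq_len(nrep)]) -
                     (tg_cal[seq_len(nrep)] - rf_cal[seq_len(nrep)]))
  structure(list(feature_id = target, delta_delta_ct = ddct,
                 fold_change = 2^-ddct, replicate_folds = rep_folds,
                 calibrator = calibrator),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%s: ddCt = %.3f, fold change = %.3f (vs %s)\n",
              x$feature_id, x$delta_delta_ct, x$fold_change, x$calibrator))
  invisible(x)
}

#' Direction concordance between qPCR and sequencing
#'
#' Compares the sign of each qPCR log2 fold change with the sign of the
#' sequencing log fold change; concordant iff the signs are equal and both
#' non-zero.
#'
#' @param folds A list of [delta_delta_ct()] results (or a single one).
#' @param de A `de_result` covering the same features.
#' @return A data.frame (`feature_id`, `qpcr_log2_fold`, `ngs_logfc`,
#'   `qpcr_direction`, `ngs_direction`, `concordant`).
#' @export
qpcr_concordance <- function(folds, de) {
  if (inherits(folds, "fold_change")) folds <- list(folds)
  fid <- vapply(folds, `[[`, character(1), "feature_id")
  miss <- setdiff(fid, de$feature_id)
  if (length(miss))
    stop("feature(s) absent from the DE result: ", paste(miss, collapse = ", "),
         call. = FALSE)
  qfold <- vapply(folds, function(f) log2(f$fold_change), numeric(1))
  lfc <- de$logfc[match(fid, de$feature_id)]
  dir_of <- function(v) ifelse(v > 0, "up", ifelse(v < 0, "down", "none"))
  data.frame(feature_id = fid,
             qpcr_log2_fold = qfold, ngs_logfc = lfc,
             qpcr_direction = dir_of(qfold), ngs_direction = dir_of(lfc),
             concordant = sign(qfold) == sign(lfc) & qfold != 0 & lfc != 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
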