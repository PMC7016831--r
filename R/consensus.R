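#' Significant-feature set for one contrast
#'
#' Extracts the features called significant in a `de_result` under the
#' configured rule (raw or BH-adjusted p below `alpha`).
#'
#' @param de A `de_result` (see [nb_exact_test()]).
#' @param alpha Significance level.
#' @param use_adjusted Use `adjusted_p` instead of `p_value`.
#' @return Character vector of significant feature ids.
#' @export
significant_features <- function(de, alpha = 0.05, use_adjusted = FALSE) {
  p <- if (use_adjusted) de$adjusted_p else de$p_value
  de$feature_id[!is.na(p) & p < alpha]
}

#' Partition four contrast sets into Venn regions
#'
#' Assigns every feature in the union of the four significant sets to
#' exactly one of the 15 membership regions of a four-set Venn diagram
#' (the classic four-contrast layout: sensitive-vs-MDR in cells and EVs of
#' two tumor models).
#'
#' @param sets Named list of exactly four character vectors.
#' @return A data.frame (`region`, `n`) with one row per region (regions
#'   labelled by the member set names joined with `&`), all 15 regions
#'   present; `sum(n)` equals the union size.
#' @export
venn_partition <- function(sets) {
  if (length(sets) != 4L || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("venn_partition expects a named list of four sets", call. = FALSE)
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0), 0, 4, dimnames = list(NULL, nm))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1L, , drop = FALSE]
  region <- apply(combos, 1L, function(z) paste(nm[as.logical(z)], collapse = "&"))
  key <- apply(member, 1L, function(z) paste(nm[z], collapse = "&"))
  cnt <- table(factor(key, levels = region))
  data.frame(region = region, n = as.integer(cnt), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-model directional consensus
#'
#' Retains features significant in both tumor models with the same sign of
#' log2 fold change — the logic behind a table of transcripts "identically
#' regulated" in the two models. Features tested in only one model are
#' excluded and counted.
#'
#' @param de_model1,de_model2 `de_result` objects for the same compartment
#'   in the two models.
#' @param alpha Significance level (applied in each model).
#' @param use_adjusted Call significance on BH-adjusted p-values.
#' @param model_names Length-2 character vector naming the models.
#' @return A data.frame of class `consensus_table` with columns
#'   `feature_id`, `logfc_<model1>`, `p_<model1>`, `logfc_<model2>`,
#'   `p_<model2>`, `direction` (`"up_in_MDR"`/`"down_in_MDR"`); attribute
#'   `n_tested_one_model` counts features tested in only one model.
#' @export
directional_consensus <- function(de_model1, de_model2, alpha = 0.05,
                                  use_adjusted = FALSE,
                                  model_names = c("NSCLC", "CML")) {
  m <- merge(de_model1[, c("feature_id", "logfc", "p_value", "adjusted_p", "tested")],
             de_model2[, c("feature_id", "logfc", "p_value", "adjusted_p", "tested")],
             by = "feature_id", suffixes = c("_1", "_2"))
  one_sided <- sum(xor(m$tested_1, m$tested_2))
  p1 <- if (use_adjusted) m$adjusted_p_1 else m$p_value_1
  p2 <- if (use_adjusted) m$adjusted_p_2 else m$p_value_2
  hit <- m$tested_1 & m$tested_2 & !is.na(p1) & !is.na(p2) &
    p1 < alpha & p2 < alpha &
    sign(m$logfc_1) == sign(m$logfc_2) & m$logfc_1 != 0
  out <- data.frame(feature_id = m$feature_id[hit],
                    logfc_1 = m$logfc_1[hit], p_1 = p1[hit],
                    logfc_2 = m$logfc_2[hit], p_2 = p2[hit],
                    direction = ifelse(m$logfc_1[hit] > 0, "up_in_MDR", "down_in_MDR"),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0(c("logfc_", "p_"), model_names[1L]),
                       paste0(c("logfc_", "p_"), model_names[2L]))
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "use_adjusted") <- use_adjusted
  attr(out, "n_tested_one_model") <- one_sided
  out
}

#' Per-sample biotype read composition
#'
#' Fraction of each sample's reads attributed to each transcript biotype
#' (the pie-chart view of mapped-read composition). Features missing from
#' the annotation are assigned biotype `"other"`.
#'
#' @param x A [count_matrix()].
#' @param annotation Annotation data.frame (`feature_id`, `biotype`).
#' @return A numeric matrix, biotypes x samples, columns summing to 1.
#' @export
biotype_composition <- function(x, annotation) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("zero-count sample(s): ", paste(colnames(x$counts)[lib == 0], collapse = ", "),
         call. = FALSE)
  bt <- annotation$biotype[match(rownames(x$counts), annotation$feature_id)]
  bt[is.na(bt)] <- "other"
  agg <- rowsum(x$counts, group = bt)
  t(t(agg) / lib)
}

#' Join consensus miRs against a local miR-to-target mapping
#'
#' Inner join of a consensus table with a user-supplied two-column mapping
#' (miR id, target gene); miRs without any mapping are reported separately.
#' External target databases are not queried.
#'
#' @param consensus A [directional_consensus()] table.
#' @param mapping A data.frame whose first two columns are miR id and
#'   target gene.
#' @return A list with `joined` (one row per miR-target pair, consensus
#'   columns carried along) and `unmapped` (character vector of miR ids).
#' @export
map_targets <- function(consensus, mapping) {
  if (!is.data.frame(mapping) || ncol(mapping) < 2L)
    stop("mapping must be a data.frame with at least two columns (miR, target)",
         call. = FALSE)
  map <- mapping[, 1:2]
  names(map) <- c("feature_id", "target")
  joined <- merge(as.data.frame(consensus), map, by = "feature_id")
  joined <- joined[order(joined$feature_id, joined$target), , drop = FALSE]
  rownames(joined) <- NULL
  list(joined = joined,
       unmapped = setdiff(consensus$feature_id, map$feature_id))
}
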