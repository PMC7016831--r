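#' @keywords internal
"_PACKAGE"

MODEL_LEVELS       <- c("NSCLC", "CML")
COMPARTMENT_LEVELS <- c("cell", "EV")
PHENOTYPE_LEVELS   <- c("sensitive", "MDR")

#' Construct a validated count matrix with sample metadata
#'
#' The central container of the pipeline: an integer feature-by-sample count
#' matrix together with typed per-sample metadata describing the study design
#' (tumor model, compartment, drug-response phenotype, replicate).
#'
#' @param counts Integer matrix, features in rows and samples in columns.
#'   Row names are taken as feature identifiers when `feature_ids` is missing.
#' @param samples A `data.frame` with one row per column of `counts` and
#'   columns `label`, `model` (`"NSCLC"`/`"CML"`), `compartment`
#'   (`"cell"`/`"EV"`), `phenotype` (`"sensitive"`/`"MDR"`) and `replicate`
#'   (integer >= 1). `label` must match the column names of `counts`.
#' @param feature_ids Optional character vector of feature identifiers
#'   overriding `rownames(counts)`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with feature ids as row names and sample labels as
#'   column names) and `samples` (the metadata data.frame).
#' @examples
#' cm <- count_matrix(
#'   matrix(0:3, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))),
#'   data.frame(label = c("s1", "s2"), model = "NSCLC", compartment = "cell",
#'              phenotype = c("sensitive", "MDR"), replicate = 1L))
#' dim(cm)
#' @export
count_matrix <- function(counts, samples, feature_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(feature_ids)) rownames(counts) <- feature_ids
  if (is.null(rownames(counts)))
    stop("count_matrix: counts must carry feature ids as row names", call. = FALSE)
  x <- structure(list(counts = counts, samples = as.data.frame(samples)),
                 class = "count_matrix")
  validate_count_matrix(x)
}

validate_count_matrix <- function(x) {
  counts <- x$counts
  samples <- x$samples
  fid <- rownames(counts)
  if (anyDuplicated(fid))
    stop("duplicate feature_id: ", paste(unique(fid[duplicated(fid)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(counts))
    stop("counts must be numeric; got mode '", mode(counts), "'", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("counts must be non-negative integers; offending value %s at feature '%s', sample '%s'",
                 format(counts[bad[1L]]), fid[i[1L]], colnames(counts)[i[2L]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  need <- c("label", "model", "compartment", "phenotype", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples$label <- as.character(samples$label)
  samples$model <- as.character(samples$model)
  samples$compartment <- as.character(samples$compartment)
  samples$phenotype <- as.character(samples$phenotype)
  samples$replicate <- as.integer(samples$replicate)
  for (col in c("model", "compartment", "phenotype")) {
    lev <- switch(col, model = MODEL_LEVELS, compartment = COMPARTMENT_LEVELS,
                  phenotype = PHENOTYPE_LEVELS)
    bad <- setdiff(unique(samples[[col]]), lev)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (expected %s)", col,
                   paste(bad, collapse = ", "), paste(lev, collapse = "/")),
           call. = FALSE)
  }
  if (any(samples$replicate < 1L))
    stop("replicate numbers must be >= 1", call. = FALSE)
  if (anyDuplicated(samples$label))
    stop("duplicate sample label: ",
         paste(unique(samples$label[duplicated(samples$label)]), collapse = ", "),
         call. = FALSE)
  key <- interaction(samples$model, samples$compartment, samples$phenotype,
                     samples$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (model, compartment, phenotype, replicate) combination: ",
         paste(unique(as.character(key)[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop(sprintf("metadata has %d rows but counts has %d columns",
                 nrow(samples), ncol(counts)), call. = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- samples$label
  if (!identical(colnames(counts), samples$label)) {
    off <- which(colnames(counts) != samples$label)[1L]
    stop(sprintf("metadata labels do not match count columns (first mismatch at column %d: '%s' vs '%s')",
                 off, colnames(counts)[off], samples$label[off]), call. = FALSE)
  }
  rownames(samples) <- NULL
  x$counts <- counts
  x$samples <- samples
  x
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(model = x$samples$model, compartment = x$samples$compartment,
               phenotype = x$samples$phenotype)
  print(tab)
  invisible(x)
}

#' Feature identifiers of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of feature ids, in matrix row order.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file is tab-separated with a mandatory header whose first column
#' is `feature_id`; remaining columns are samples. The metadata file is
#' tab-separated with columns `label`, `model`, `compartment`, `phenotype`,
#' `replicate`, keyed to the count columns by `label`.
#'
#' @param path Path to the counts TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @return A validated [count_matrix()]; row and column order are preserved
#'   from the files.
#' @export
read_count_matrix <- function(path, metadata_path) {
  for (p in c(path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1L] != "feature_id")
    stop("counts file must have a 'feature_id' first column and at least one sample column: ",
         path, call. = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- as.character(tab$feature_id)
  miss <- setdiff(meta$label, colnames(counts))
  if (length(miss))
    stop("metadata label(s) absent from counts columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(colnames(counts), meta$label)
  if (length(extra))
    stop("count column(s) missing from metadata: ", paste(extra, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(counts), meta$label), , drop = FALSE]
  count_matrix(counts, meta)
}

#' Write a count matrix and its metadata to TSV files
#'
#' Inverse of [read_count_matrix()]; a write/read round trip reproduces the
#' object exactly.
#'
#' @param x A `count_matrix`.
#' @param path Output path for the counts TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a feature annotation table
#'
#' Tab-separated with header `feature_id`, `name`, `biotype`. Biotype values
#' are free text (conventionally `miRNA`, `pseudogene`, `protein_coding`,
#' `rRNA`, `tRNA`, `snRNA`, `other`); unknown labels are preserved verbatim.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with one row per feature.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "name", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$feature_id))
    stop("duplicate feature_id in annotation: ",
         paste(unique(ann$feature_id[duplicated(ann$feature_id)]), collapse = ", "),
         call. = FALSE)
  ann
}

#' Write a feature annotation table
#' @param ann Annotation `data.frame` (`feature_id`, `name`, `biotype`).
#' @param path Output path.
#' @return Invisibly, `ann`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Subset a count matrix by design factors
#'
#' Restricts a `count_matrix` to the samples matching the requested tumor
#' model, compartment and (optionally) phenotype. The feature set is never
#' changed; downstream stages always receive explicit subsets.
#'
#' @param x A `count_matrix`.
#' @param model `"NSCLC"` or `"CML"`, or `NULL` to keep both.
#' @param compartment `"cell"` or `"EV"`, or `NULL`.
#' @param phenotype `"sensitive"` or `"MDR"`, or `NULL`.
#' @return A `count_matrix` with the matching samples.
#' @export
subset_samples <- function(x, model = NULL, compartment = NULL, phenotype = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rep(TRUE, nrow(x$samples))
  for (sel in list(list("model", model, MODEL_LEVELS),
                   list("compartment", compartment, COMPARTMENT_LEVELS),
                   list("phenotype", phenotype, PHENOTYPE_LEVELS))) {
    if (is.null(sel[[2L]])) next
    if (!all(sel[[2L]] %in% sel[[3L]]))
      stop(sprintf("invalid %s value: %s", sel[[1L]],
                   paste(setdiff(sel[[2L]], sel[[3L]]), collapse = ", ")), call. = FALSE)
    keep <- keep & x$samples[[sel[[1L]]]] %in% sel[[2L]]
  }
  if (!any(keep)) stop("no samples match the requested subset", call. = FALSE)
  count_matrix(x$counts[, keep, drop = FALSE], x$samples[keep, , drop = FALSE])
}
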