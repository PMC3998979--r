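#' Assemble a multi-library expression matrix
#'
#' Rows are the union of all genes seen in any library; absent gene-library
#' pairs are zero. TPM is recomputed per library from the mapped totals, so
#' every TPM column sums to 1e6 over nonzero rows.
#'
#' @param mappings list of [map_library()] results with unique library ids.
#' @param metadata optional data.frame with columns `library_id`,
#'   `genotype`, `stage`; required by [stage_filter()] and the comparison
#'   helpers.
#' @return an `expr_matrix`: list with `counts` and `tpm` (gene x library
#'   matrices), `library_info`, `library_totals`.
#' @export
assemble <- function(mappings, metadata = NULL) {
  if (length(mappings) < 1) .stopf("need at least one library")
  ids <- vapply(mappings, `[[`, character(1), "library_id")
  if (anyDuplicated(ids)) .stopf("duplicate library id: %s",
                                 ids[duplicated(ids)][1])
  genes <- sort(unique(unlist(lapply(mappings, function(m)
    names(m$gene_counts)), use.names = FALSE)))
  counts <- matrix(0, length(genes), length(ids),
                   dimnames = list(genes, ids))
  totals <- stats::setNames(numeric(length(ids)), ids)
  for (m in mappings) {
    counts[names(m$gene_counts), m$library_id] <- m$gene_counts
    totals[m$library_id] <- m$mapped_clean_total
  }
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  if (!is.null(metadata)) {
    if (!all(c("library_id", "genotype", "stage") %in% names(metadata)))
      .stopf("metadata needs columns library_id, genotype, stage")
    metadata <- metadata[match(ids, metadata$library_id),
                         c("library_id", "genotype", "stage")]
    if (anyNA(metadata$library_id))
      .stopf("metadata is missing some library ids")
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, tpm = tpm, library_info = metadata,
                 library_totals = totals), class = "expr_matrix")
}

#' Keep genes expressed in enough libraries of at least one stage
#'
#' A gene passes when, for some stage, at least `min_libraries` libraries of
#' that stage show TPM above `expression_threshold`. With the defaults
#' (3 libraries, threshold 0) this is the "expressed in at least three
#' libraries at one stage" filter used before profile clustering.
#'
#' @param matrix an [assemble()] result with stage metadata.
#' @param min_libraries minimum libraries per stage (>= 1).
#' @param expression_threshold TPM floor defining "expressed" (exclusive).
#' @return the filtered `expr_matrix` (same structure, fewer rows).
#' @export
stage_filter <- function(matrix, min_libraries = 3, expression_threshold = 0) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (is.null(matrix$library_info)) .stopf("stage metadata missing")
  if (min_libraries < 1) .stopf("min_libraries must be >= 1")
  stages <- unique(matrix$library_info$stage)
  keep <- rep(FALSE, nrow(matrix$tpm))
  for (st in stages) {
    cols <- matrix$library_info$library_id[matrix$library_info$stage == st]
    n_expr <- rowSums(matrix$tpm[, cols, drop = FALSE] > expression_threshold)
    keep <- keep | (n_expr >= min_libraries)
  }
  out <- matrix
  out$counts <- matrix$counts[keep, , drop = FALSE]
  out$tpm <- matrix$tpm[keep, , drop = FALSE]
  out
}

#' Log2-transform a TPM matrix for clustering
#'
#' @param matrix an `expr_matrix` (or a plain numeric matrix of TPM).
#' @param pseudo additive TPM offset; must be > 0 if zeros are present.
#' @return numeric matrix of `log2(TPM + pseudo)`.
#' @export
log_transform <- function(matrix, pseudo = 1) {
  tpm <- if (inherits(matrix, "expr_matrix")) matrix$tpm else matrix
  if (any(tpm == 0) && pseudo <= 0)
    .stopf("pseudo must be > 0 when zero TPM values are present")
  log2(tpm + pseudo)
}

#' Write / read an expression matrix as TSV
#'
#' Header row of library ids, leading `gene_id` column; genotype/stage
#' metadata goes to a sidecar TSV.
#'
#' @param matrix an `expr_matrix`.
#' @param path output TSV for the TPM matrix.
#' @param what `"tpm"` or `"counts"`.
#' @param metadata_path optional sidecar TSV for library metadata.
#' @export
write_matrix_tsv <- function(matrix, path, what = c("tpm", "counts"),
                             metadata_path = NULL) {
  what <- match.arg(what)
  m <- matrix[[what]]
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(metadata_path) && !is.null(matrix$library_info))
    write_tsv(matrix$library_info, metadata_path)
  invisible(path)
}
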