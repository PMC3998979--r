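#' Exact two-library tag-count test
#'
#' Significance of a count difference between two libraries without
#' replicates, in the Audic-Claverie tradition: condition on the total
#' `x + y` tags observed for the gene, under the null the `y` tags of
#' library B are a binomial draw with success probability `N2 / (N1 + N2)`
#' set by the library sizes. The two-sided p-value is twice the smaller
#' tail at the observed split, capped at 1.
#'
#' Computed via the regularized-incomplete-beta route of `pbinom()`, which
#' is numerically stable for totals far beyond 1e4.
#'
#' @param x,y tag counts of the gene in libraries A and B (vectorized).
#' @param n1,n2 total mapped tags of libraries A and B (> 0).
#' @return p-values in \[0, 1\].
#' @export
exact_tag_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) .stopf("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) .stopf("library totals must be positive")
  p2 <- n2 / (n1 + n2)
  n <- x + y
  lower <- stats::pbinom(y, n, p2)
  upper <- stats::pbinom(y - 1, n, p2, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg step-up adjusted p-values (q-values)
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )` over the sorted p-values,
#' capped at 1; monotone in p.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    .stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ranked <- m / (m:1) * p_values[o]        # m*p_(j)/rank(j), largest first
  q <- pmin(1, cummin(ranked))
  q[order(o)]
}

#' Build per-gene comparison records for two libraries
#'
#' @param matrix an [assemble()] result.
#' @param lib_a,lib_b library ids; A is the baseline (e.g. the recipient
#'   genotype), log2 ratios are B over A.
#' @param pseudo_tpm offset added to both TPMs before the ratio so genes
#'   with a zero count remain reportable.
#' @return data.frame of records (gene_id, counts, TPMs, log2_ratio,
#'   p_value), one row per gene with a nonzero count in either library.
#' @export
dge_records <- function(matrix, lib_a, lib_b, pseudo_tpm = 0.5) {
  stopifnot(inherits(matrix, "expr_matrix"))
  for (l in c(lib_a, lib_b))
    if (!l %in% colnames(matrix$counts)) .stopf("unknown library '%s'", l)
  x <- matrix$counts[, lib_a]
  y <- matrix$counts[, lib_b]
  keep <- x + y > 0
  x <- x[keep]; y <- y[keep]
  n1 <- matrix$library_totals[[lib_a]]
  n2 <- matrix$library_totals[[lib_b]]
  tpm_a <- 1e6 * x / n1
  tpm_b <- 1e6 * y / n2
  data.frame(
    gene_id = rownames(matrix$counts)[keep],
    count_a = unname(x), count_b = unname(y),
    tpm_a = unname(tpm_a), tpm_b = unname(tpm_b),
    log2_ratio = unname(log2((tpm_b + pseudo_tpm) / (tpm_a + pseudo_tpm))),
    p_value = unname(exact_tag_test(x, y, n1, n2)),
    stringsAsFactors = FALSE)
}

#' Call differentially expressed genes within one comparison
#'
#' Adjusts the records' p-values with Benjamini-Hochberg within this
#' comparison, then flags genes with `q <= fdr_max` and
#' `|log2_ratio| >= min_abs_log2` (both thresholds inclusive). Direction is
#' `up` when the ratio is positive (higher in library B), else `down`.
#'
#' @param records a [dge_records()] data.frame (needs `p_value` and
#'   `log2_ratio`).
#' @param fdr_max FDR ceiling (default 0.001).
#' @param min_abs_log2 minimum absolute log2 ratio (default 1).
#' @param label comparison label.
#' @return a `dge_comparison`: list with `label`, `records` (with q_value,
#'   is_deg, direction columns added), `n_up`, `n_down`.
#' @export
call_degs <- function(records, fdr_max = 0.001, min_abs_log2 = 1,
                      label = "comparison") {
  records$q_value <- bh_adjust(records$p_value)
  records$is_deg <- records$q_value <= fdr_max &
    abs(records$log2_ratio) >= min_abs_log2
  records$direction <- ifelse(records$log2_ratio > 0, "up", "down")
  structure(list(
    label = label,
    records = records,
    n_up = sum(records$is_deg & records$direction == "up"),
    n_down = sum(records$is_deg & records$direction == "down")
  ), class = "dge_comparison")
}

#' Compare two libraries end to end
#'
#' Convenience wrapper: [dge_records()] then [call_degs()].
#'
#' @inheritParams dge_records
#' @inheritParams call_degs
#' @return a `dge_comparison`.
#' @export
compare_libraries <- function(matrix, lib_a, lib_b, fdr_max = 0.001,
                              min_abs_log2 = 1, pseudo_tpm = 0.5,
                              label = NULL) {
  call_degs(dge_records(matrix, lib_a, lib_b, pseudo_tpm),
            fdr_max, min_abs_log2,
            label = label %||% paste0(lib_b, "_vs_", lib_a))
}

#' DEG set of a comparison
#' @param comparison a `dge_comparison`.
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @export
deg_set <- function(comparison, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  r <- comparison$records
  keep <- r$is_deg
  if (direction != "any") keep <- keep & r$direction == direction
  r$gene_id[keep]
}

#' Venn regions of DEG sets across comparisons
#'
#' Partitions the union of DEG sets into exclusive membership regions
#' ("A", "A&B", ...). In the `same_direction_*` modes a gene counts as a
#' member of a comparison only when it is a DEG with the stated direction
#' there, so the all-comparisons region is the common same-direction DEG
#' set.
#'
#' @param comparisons named list of `dge_comparison` objects (>= 2).
#' @param mode `"any_direction"`, `"same_direction_up"` or
#'   `"same_direction_down"`.
#' @return list with `regions` (named list of gene id vectors, names are
#'   `&`-joined comparison labels), `sizes`, and `common` (genes present in
#'   every comparison).
#' @export
common_degs <- function(comparisons,
                        mode = c("any_direction", "same_direction_up",
                                 "same_direction_down")) {
  mode <- match.arg(mode)
  if (length(comparisons) < 2) .stopf("need at least two comparisons")
  labels <- names(comparisons) %||%
    vapply(comparisons, `[[`, character(1), "label")
  dirn <- switch(mode, any_direction = "any",
                 same_direction_up = "up", same_direction_down = "down")
  sets <- lapply(comparisons, deg_set, direction = dirn)
  names(sets) <- labels
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(all_genes) == 0)
    return(list(regions = list(), sizes = integer(0), common = character(0)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) paste(labels[m], collapse = "&"))
  regions <- split(all_genes, pattern)
  common <- all_genes[rowSums(member) == length(sets)]
  list(regions = regions, sizes = vapply(regions, length, integer(1)),
       common = common)
}

#' Relative expression from a qPCR cycle-threshold difference
#'
#' The standard `2^-dCt` transform: a target one cycle later than the
#' normalizer has relative level 0.5.
#'
#' @param delta_ct numeric Ct difference (target minus reference gene).
#' @return `2^(-delta_ct)`.
#' @export
relative_expression <- function(delta_ct) 2^(-delta_ct)

#' Write a comparison table as TSV
#' @param comparison a `dge_comparison`.
#' @param path output file.
#' @export
write_comparison_tsv <- function(comparison, path) {
  write_tsv(comparison$records, path)
}

#' @export
print.dge_comparison <- function(x, ...) {
  cat(sprintf("%s: %d genes tested, %d DEGs (%d up, %d down)\n", x$label,
              nrow(x$records), x$n_up + x$n_down, x$n_up, x$n_down))
  invisible(x)
}
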