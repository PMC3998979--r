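#' Build an annotation map from a gene-to-term table
#'
#' @param annotation data.frame with columns `gene_id`, `term_id` (e.g.
#'   from [read_annotation()] or [make_annotation()]).
#' @param universe optional character vector restricting the gene universe;
#'   defaults to all annotated genes (the convention when enrichment is
#'   reported against "reference genes with pathway annotation").
#' @return an `annotation_map`: list with `terms` (named list term ->
#'   gene ids) and `universe`.
#' @export
annotation_map <- function(annotation, universe = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  terms <- lapply(split(annotation$gene_id, annotation$term_id), unique)
  uni <- sort(unique(if (is.null(universe)) annotation$gene_id else universe))
  if (length(uni) == 0) .stopf("annotation universe is empty")
  if (!is.null(universe))
    terms <- lapply(terms, intersect, y = uni)
  structure(list(terms = terms, universe = uni), class = "annotation_map")
}

#' Term over-representation of a gene set
#'
#' One-sided hypergeometric test per term: with `N` universe genes of which
#' `K` carry the term, and `n` set genes inside the universe, the p-value
#' is the upper-tail probability of seeing at least the observed `k`
#' term-carrying set genes. q-values are Benjamini-Hochberg across the
#' tested terms; `ratio` is the percentage `100 * k / K` (rounded half-up
#' to two decimals), the column printed alongside pathway tables.
#'
#' Genes outside the universe are dropped from `n` (a message reports how
#' many).
#'
#' @param deg_set character vector of gene ids (e.g. [deg_set()]).
#' @param annotation an [annotation_map()].
#' @param report_zero_k keep terms with no set gene (default FALSE).
#' @return data.frame with columns term_id, k, K, n, N, ratio, p_value,
#'   q_value, ordered by p-value.
#' @export
enrich <- function(deg_set, annotation, report_zero_k = FALSE) {
  stopifnot(inherits(annotation, "annotation_map"))
  N <- length(annotation$universe)
  inside <- unique(deg_set[deg_set %in% annotation$universe])
  dropped <- length(unique(deg_set)) - length(inside)
  if (dropped > 0)
    message(dropped, " gene(s) outside the annotation universe dropped")
  if (length(inside) == 0) .stopf("gene set does not intersect the universe")
  n <- length(inside)
  K <- vapply(annotation$terms, length, integer(1))
  k <- vapply(annotation$terms, function(g) sum(inside %in% g), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(annotation$terms), k = k, K = K,
                    n = n, N = N,
                    ratio = round_half_up(100 * k / K),
                    p_value = p, q_value = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!report_zero_k) out <- out[out$k > 0, , drop = FALSE]
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Per-cluster term enrichment
#'
#' Runs [enrich()] once per cluster, treating each cluster's gene set as
#' the query set -- the computation behind "cluster G3 is enriched in
#' protein catabolism" style summaries.
#'
#' @param assignment named integer labels (gene -> cluster).
#' @param annotation an [annotation_map()].
#' @param report_zero_k forwarded to [enrich()].
#' @return named list of [enrich()] data.frames, one per cluster label.
#' @export
cluster_function_profile <- function(assignment, annotation,
                                     report_zero_k = FALSE) {
  ks <- sort(unique(assignment))
  out <- lapply(ks, function(k)
    enrich(names(assignment)[assignment == k], annotation, report_zero_k))
  names(out) <- ks
  out
}

#' Write an enrichment table as TSV
#' @param rows an [enrich()] data.frame.
#' @param path output file.
#' @export
write_enrichment_tsv <- function(rows, path) write_tsv(rows, path)
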