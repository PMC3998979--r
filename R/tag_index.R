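#' Build a CATG-anchored 21-base tag index
#'
#' Scans every reference transcript for CATG anchor sites and records each
#' 21-base window (the anchor plus 17 downstream bases) as a tag keyed by
#' sequence. All qualifying anchor positions are indexed, not only the
#' 3'-most, because reverse-transcription and partial-digestion artifacts in
#' real libraries produce internal-site tags. Windows containing N are
#' skipped. Offsets are 0-based and refer to the strand on which the tag was
#' read: for `strand == "-"` the offset indexes into the reverse complement
#' of the transcript.
#'
#' @param reference `DNAStringSet` or named character vector of transcripts
#'   (uppercase ACGTN).
#' @param strands `"sense"` (default; DGE chemistry reads the sense strand)
#'   or `"both"` for sensitivity analysis.
#' @return a `tag_index`: list with `entries` (data.frame tag/gene_id/offset/
#'   strand), `genes_by_tag` (named list: tag -> unique gene ids), `keys`,
#'   `n_genes` (reference size), `genes_touched`, `n_tag_positions`.
#' @export
build_index <- function(reference, strands = c("sense", "both")) {
  strands <- match.arg(strands)
  if (length(reference) == 0) .stopf("reference must be non-empty")
  seqs <- .as_ref_character(reference)
  if (any(grepl("[^ACGTN]", seqs)))
    .stopf("reference sequences must be uppercase over ACGTN")

  scan_strand <- function(s, strand_flag) {
    parts <- lapply(seq_along(s), function(i) {
      hits <- gregexpr("CATG", s[[i]], fixed = TRUE)[[1]]
      if (hits[1] == -1) return(NULL)
      hits <- hits[hits + 20L <= nchar(s[[i]])]
      if (length(hits) == 0) return(NULL)
      tags <- substring(s[[i]], hits, hits + 20L)
      keep <- !grepl("N", tags, fixed = TRUE)
      if (!any(keep)) return(NULL)
      data.frame(tag = tags[keep], gene_id = names(s)[i],
                 offset = hits[keep] - 1L, strand = strand_flag,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }

  entries <- scan_strand(seqs, "+")
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    names(rc) <- names(seqs)
    entries <- rbind(entries, scan_strand(rc, "-"))
  }
  if (is.null(entries))
    entries <- data.frame(tag = character(0), gene_id = character(0),
                          offset = integer(0), strand = character(0))
  # canonical order: keyed by sequence, so record order in the FASTA does
  # not affect index content
  entries <- entries[order(entries$tag, entries$gene_id, entries$offset,
                           entries$strand), , drop = FALSE]
  rownames(entries) <- NULL
  genes_by_tag <- lapply(split(entries$gene_id, entries$tag), unique)
  # fast path for mapping: the gene when a key is gene-unique, NA otherwise
  unique_gene <- vapply(genes_by_tag, function(g)
    if (length(g) == 1L) g else NA_character_, character(1))

  structure(list(
    entries = entries,
    genes_by_tag = genes_by_tag,
    unique_gene = unique_gene,
    keys = names(genes_by_tag),
    n_genes = length(seqs),
    genes_touched = sort(unique(entries$gene_id)),
    n_tag_positions = nrow(entries)
  ), class = "tag_index")
}

#' Per-gene tag sets
#'
#' @param index a [build_index()] result.
#' @param gene_ids optional gene ids to report; genes absent from the index
#'   map to the empty set.
#' @return named list: gene id -> character vector of distinct tags.
#' @export
gene_tag_sets <- function(index, gene_ids = NULL) {
  stopifnot(inherits(index, "tag_index"))
  sets <- lapply(split(index$entries$tag, index$entries$gene_id), unique)
  if (is.null(gene_ids)) return(sets)
  out <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  for (g in gene_ids) out[[g]] <- sets[[g]] %||% character(0)
  out
}

#' Serialize a tag index to sorted TSV for inspection/diffing
#' @param index a `tag_index`.
#' @param path output file.
#' @export
write_index_tsv <- function(index, path) {
  write_tsv(index$entries, path)
}

#' @export
print.tag_index <- function(x, ...) {
  cat("CATG tag index:", length(x$keys), "distinct tags,",
      x$n_tag_positions, "positions,",
      length(x$genes_touched), "of", x$n_genes, "genes represented\n")
  invisible(x)
}
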