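#' Filter a raw tag library to clean tags
#'
#' Applies the standard DGE quality filters: drop tags that are not the full
#' 21-nt length, drop tags containing ambiguous bases (N), and drop
#' low-copy tags below `min_count` (default 2, i.e. singletons are removed).
#'
#' @param raw a `raw_tag_library` (see [read_tag_file()] /
#'   [simulate_library()]), or a data.frame of (tag, count).
#' @param min_count minimum library count for a tag to be kept.
#' @param library_id optional label override.
#' @return a `tag_library`: list with `library_id`, `raw_total`,
#'   `distinct_raw`, `clean_total`, `distinct_clean` and `clean_tags`
#'   (data.frame tag/count).
#' @export
clean_tags <- function(raw, min_count = 2, library_id = NULL) {
  if (is.data.frame(raw)) raw <- list(library_id = library_id %||% "library",
                                      tags = raw)
  df <- raw$tags
  if (nrow(df) > 0 && any(grepl("[^ACGTN]", df$tag)))
    .stopf("raw tags must be strings over ACGTN")
  keep <- nchar(df$tag) == 21L & !grepl("N", df$tag, fixed = TRUE) &
    df$count >= min_count
  clean <- df[keep, , drop = FALSE]
  rownames(clean) <- NULL
  structure(list(
    library_id = library_id %||% raw$library_id,
    raw_total = sum(df$count),
    distinct_raw = nrow(df),
    clean_total = sum(clean$count),
    distinct_clean = nrow(clean),
    clean_tags = clean
  ), class = "tag_library")
}

#' Map clean tags to genes through a tag index
#'
#' A tag is matched exactly against the index keys first; only if it has no
#' exact match and `max_mismatch == 1` is its one-mismatch neighborhood
#' searched. Mismatches are never allowed inside the CATG anchor (the anchor
#' is enzymatic, not read-derived), so the neighborhood is the 3 x 17 = 51
#' single-substitution variants of positions 5-21. A tag whose matched keys
#' span more than one distinct gene is ambiguous and contributes to no gene;
#' multiple positions within one gene are fine and are summed.
#'
#' @param clean a [clean_tags()] result.
#' @param index a [build_index()] result.
#' @param max_mismatch 0 or 1.
#' @return a `mapping_result`: list with `library_id`, `gene_counts` (named
#'   numeric), `mapped_clean_total`, `distinct_mapped`, `ambiguous_distinct`,
#'   `unmapped_distinct`, `genes_hit`.
#' @export
map_library <- function(clean, index, max_mismatch = 1) {
  stopifnot(inherits(index, "tag_index"))
  if (!max_mismatch %in% c(0, 1)) .stopf("max_mismatch must be 0 or 1")
  tags <- clean$clean_tags$tag
  counts <- clean$clean_tags$count
  if (length(tags) > 0 && any(nchar(tags) != 21L))
    .stopf("all clean tags must be exactly 21 nt")

  gene_of <- rep(NA_character_, length(tags))  # NA = unmapped
  ambiguous <- logical(length(tags))

  exact <- match(tags, index$keys)
  hit <- which(!is.na(exact))
  gene_of[hit] <- index$unique_gene[exact[hit]]
  ambiguous[hit] <- is.na(gene_of[hit])

  if (max_mismatch == 1) {
    todo <- which(is.na(exact))
    if (length(todo) > 0) {
      variants <- .one_mismatch_variants(tags[todo])  # 51 x n matrix
      vmatch <- match(variants, index$keys)
      dim(vmatch) <- dim(variants)
      for (j in which(colSums(!is.na(vmatch)) > 0)) {
        keys_hit <- vmatch[, j]
        keys_hit <- keys_hit[!is.na(keys_hit)]
        genes <- unique(unlist(index$genes_by_tag[keys_hit], use.names = FALSE))
        i <- todo[j]
        if (length(genes) == 1L) gene_of[i] <- genes else ambiguous[i] <- TRUE
      }
    }
  }

  mapped <- !is.na(gene_of)
  gene_counts <- if (any(mapped))
    vapply(split(counts[mapped], gene_of[mapped]), sum, numeric(1))
  else stats::setNames(numeric(0), character(0))

  structure(list(
    library_id = clean$library_id,
    gene_counts = gene_counts,
    mapped_clean_total = sum(counts[mapped]),
    distinct_mapped = sum(mapped),
    ambiguous_distinct = sum(ambiguous),
    unmapped_distinct = sum(!mapped & !ambiguous),
    genes_hit = length(gene_counts)
  ), class = "mapping_result")
}

# all single-substitution variants outside the 4-base anchor; returns a
# 51 x n character matrix (rows = variants, columns = input tags)
.one_mismatch_variants <- function(tags) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_character_, nrow = 51L, ncol = length(tags))
  row <- 1L
  for (pos in 5:21) {
    cur <- substr(tags, pos, pos)
    for (shift in 1:3) {
      new <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
      v <- tags
      substr(v, pos, pos) <- new
      out[row, ] <- v
      row <- row + 1L
    }
  }
  out
}

#' TPM expression vector for one mapped library
#'
#' Gene expression is the sum of tags mapped to any position of the gene,
#' scaled to transcripts per million: `TPM(g) = 1e6 * count(g) / total`.
#'
#' @param mapping a [map_library()] result.
#' @return named numeric vector of TPM over genes with nonzero counts; sums
#'   to 1e6.
#' @export
gene_expression <- function(mapping) {
  if (mapping$mapped_clean_total <= 0)
    .stopf("library '%s' has zero mapped tags", mapping$library_id)
  1e6 * mapping$gene_counts / mapping$mapped_clean_total
}

#' Library-level QC summary (tag-accounting table row)
#'
#' Computes the standard per-library accounting of a tag-profiling run: raw
#' and clean totals, distinct-tag counts, mapped totals, genes hit, and the
#' three derived percentages (percent of clean tags mapped, percent of
#' distinct clean tags mapped, percent of reference genes hit), each rounded
#' half-up to two decimals as conventionally printed.
#'
#' Inputs are duck-typed: any lists carrying the named fields work, so
#' printed counts from a published table can be fed straight in.
#'
#' @param clean a [clean_tags()] result (or list with `raw_total`,
#'   `distinct_raw`, `clean_total`, `distinct_clean`).
#' @param mapping a [map_library()] result (or list with
#'   `mapped_clean_total`, `distinct_mapped`, `genes_hit`).
#' @param n_reference_genes size of the reference gene set (> 0).
#' @return a `library_qc` list with the eight count fields plus
#'   `pct_clean_mapped`, `pct_distinct_mapped`, `pct_reference_genes`.
#' @export
library_qc <- function(clean, mapping, n_reference_genes) {
  if (is.null(n_reference_genes) || n_reference_genes <= 0)
    .stopf("n_reference_genes must be > 0")
  if (!is.null(clean$library_id) && !is.null(mapping$library_id) &&
      !identical(clean$library_id, mapping$library_id))
    .stopf("library ids disagree: '%s' vs '%s'",
           clean$library_id, mapping$library_id)
  structure(list(
    library_id = clean$library_id %||% mapping$library_id %||% "library",
    raw_total = clean$raw_total,
    distinct_raw = clean$distinct_raw,
    clean_total = clean$clean_total,
    distinct_clean = clean$distinct_clean,
    mapped_clean_total = mapping$mapped_clean_total,
    pct_clean_mapped =
      round_half_up(100 * mapping$mapped_clean_total / clean$clean_total),
    distinct_mapped = mapping$distinct_mapped,
    pct_distinct_mapped =
      round_half_up(100 * mapping$distinct_mapped / clean$distinct_clean),
    genes_hit = mapping$genes_hit,
    pct_reference_genes =
      round_half_up(100 * mapping$genes_hit / n_reference_genes)
  ), class = "library_qc")
}

#' Write a multi-library QC table in the conventional row layout
#'
#' One column per library, rows labelled as in published tag-distribution
#' tables (Raw Data, Distinct Raw Tag, Clean Tag, ...).
#'
#' @param qcs list of [library_qc()] results.
#' @param path output TSV.
#' @export
write_qc_table <- function(qcs, path) {
  rows <- c(raw_total = "Raw Data", distinct_raw = "Distinct Raw Tag",
            clean_total = "Clean Tag", distinct_clean = "Distinct Clean Tag",
            mapped_clean_total = "Unique Clean Tag Mapping to Gene",
            pct_clean_mapped = "Total % of clean tag",
            distinct_mapped = "Unique Distinct Clean Tag Mapping to Gene",
            pct_distinct_mapped = "Total % of distinct tag",
            genes_hit = "Unambiguous Tag-mapped Genes",
            pct_reference_genes = "Percentage of reference genes")
  tab <- data.frame(Summary = unname(rows), stringsAsFactors = FALSE)
  for (qc in qcs) {
    vals <- vapply(names(rows), function(f) {
      v <- qc[[f]]
      if (grepl("^pct_", f)) sprintf("%.2f%%", v) else format(v, scientific = FALSE)
    }, character(1))
    tab[[qc$library_id]] <- unname(vals)
  }
  write_tsv(tab, path)
}

#' Write a mapping result as TSV (gene_id, count, tpm)
#' @param mapping a [map_library()] result.
#' @param path output file.
#' @export
write_mapping_tsv <- function(mapping, path) {
  tpm <- gene_expression(mapping)
  genes <- names(mapping$gene_counts)
  write_tsv(data.frame(gene_id = genes,
                       count = unname(mapping$gene_counts[genes]),
                       tpm = unname(tpm[genes])), path)
}
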