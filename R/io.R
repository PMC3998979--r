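#' Read a reference transcript set from FASTA
#'
#' Accepts wrapped or unwrapped FASTA; sequences are uppercased so indexing
#' is case-insensitive.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) .stopf("duplicate gene ids in %s", path)
  x
}

#' Write a reference transcript set as FASTA
#' @param reference `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_reference <- function(reference, path) {
  if (!inherits(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(.as_ref_character(reference))
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Read a raw tag library
#'
#' Autodetects the two supported plain-text layouts: two-column TSV
#' (tag sequence, count) or one read per line (counted on load).
#'
#' @param path input file.
#' @param library_id label for the library; defaults to the file stem.
#' @return a `raw_tag_library` (list with `library_id`, `tags` data.frame).
#' @export
read_tag_file <- function(path, library_id = NULL) {
  library_id <- library_id %||% sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    tags <- data.frame(tag = character(0), count = integer(0))
  } else if (grepl("\t", first)) {
    df <- utils::read.delim(path, header = FALSE, col.names = c("tag", "count"),
                            colClasses = c("character", "integer"))
    tags <- stats::aggregate(count ~ tag, df, sum)
  } else {
    tab <- table(readLines(path))
    tags <- data.frame(tag = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  }
  tags$tag <- toupper(tags$tag)
  structure(list(library_id = library_id, tags = tags),
            class = "raw_tag_library")
}

#' Write a raw tag library as two-column TSV (tag, count)
#' @param library a `raw_tag_library`.
#' @param path output file.
#' @export
write_tag_file <- function(library, path) {
  utils::write.table(library$tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation map from two-column TSV
#' @param path TSV with columns gene_id, term_id (no header).
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, header = FALSE, col.names = c("gene_id", "term_id"),
                    colClasses = "character")
}

#' Write a gene-to-term annotation map as two-column TSV
#' @param annotation data.frame with columns gene_id, term_id.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("gene_id", "term_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared TSV writer with a header row
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
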