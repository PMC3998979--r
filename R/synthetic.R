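#' Synthetic experimental design for tag-based DGE
#'
#' Describes an emulated tag-sequencing experiment: a set of genotypes
#' (a recipient line plus introgression lines) sampled at several
#' developmental stages, one library per genotype-stage combination.
#' Defaults emulate the scale of a cotton-fiber tag-profiling study
#' (5 genotypes x 3 stages of 15/20/25 days post-anthesis) at a depth
#' scaled down from millions to hundreds of thousands of tags so the full
#' pipeline runs in seconds.
#'
#' @param n_genes number of reference genes to simulate.
#' @param genotype_ids genotype labels; the first is the recipient/reference
#'   genotype all others are contrasted against.
#' @param stage_ids developmental stage labels.
#' @param library_depth expected number of clean tags per library.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   per genotype-stage contrast, in \[0, 1).
#' @param de_log2_effect planted absolute log2 fold change (>= 1).
#' @param dispersion negative-binomial dispersion of tag counts; 0 selects
#'   the Poisson limit.
#' @param error_rate per-base substitution error probability in \[0, 0.05\].
#' @param seed master seed; all library-level randomness is derived from it.
#' @return an object of class `synth_design`.
#' @export
synth_design <- function(n_genes = 2000,
                         genotype_ids = c("TM1", "IL1", "IL2", "IL3", "IL4"),
                         stage_ids = c("15DPA", "20DPA", "25DPA"),
                         library_depth = 2e5,
                         de_fraction = 0.1,
                         de_log2_effect = 2,
                         dispersion = 0,
                         error_rate = 0.01,
                         seed = 1L) {
  if (n_genes < 1) .stopf("n_genes must be positive")
  if (library_depth <= 0) .stopf("library_depth must be > 0")
  if (de_fraction < 0 || de_fraction >= 1) .stopf("de_fraction must be in [0, 1)")
  if (de_log2_effect < 1) .stopf("de_log2_effect must be >= 1")
  if (dispersion < 0) .stopf("dispersion must be >= 0")
  if (error_rate < 0 || error_rate > 0.05) .stopf("error_rate must be in [0, 0.05]")
  structure(list(
    n_genes = as.integer(n_genes),
    genotype_ids = as.character(genotype_ids),
    stage_ids = as.character(stage_ids),
    library_depth = library_depth,
    de_fraction = de_fraction,
    de_log2_effect = de_log2_effect,
    dispersion = dispersion,
    error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "synth_design")
}

#' Generate a synthetic reference transcript set
#'
#' Simulates transcript sequences over ACGT. A configurable fraction of
#' transcripts is guaranteed to carry at least one extractable tag site --
#' a CATG anchor followed by at least 17 bases -- and the remaining fraction
#' is guaranteed to carry none, emulating the reference genes a restriction-
#' anchored protocol can and cannot observe.
#'
#' @param n_genes number of transcripts (>= 1).
#' @param length_range integer vector `c(min, max)` of transcript lengths in
#'   bp; minimum allowed is 25.
#' @param catg_fraction fraction of transcripts carrying an extractable tag.
#' @param seed RNG seed; the same seed yields byte-identical sequences.
#' @return a named `Biostrings::DNAStringSet` with unique gene ids.
#' @export
make_reference <- function(n_genes, length_range = c(200, 1200),
                           catg_fraction = 0.97, seed = 1L) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1)
    .stopf("n_genes must be a positive integer")
  if (length(length_range) != 2 || length_range[1] < 25 ||
      length_range[2] < length_range[1])
    .stopf("length_range must be c(min, max) with min >= 25 and max >= min")
  if (catg_fraction < 0 || catg_fraction > 1)
    .stopf("catg_fraction must be in [0, 1]")
  set.seed(seed)
  n_genes <- as.integer(n_genes)
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n_genes)
          else sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))

  n_with <- round(n_genes * catg_fraction)
  with_tag <- seq_len(n_genes) %in%
    (if (n_with > 0) sample.int(n_genes, n_with) else integer(0))

  for (i in seq_len(n_genes)) {
    if (with_tag[i]) {
      if (is.na(.last_tag_site(seqs[i]))) {
        # plant an anchor at a random position leaving >= 17 downstream bases
        pos <- sample.int(lens[i] - 20L, 1)
        substr(seqs[i], pos, pos + 3L) <- "CATG"
      }
    } else {
      # destroy every extractable site; replacing the anchor G cannot be
      # allowed to create a fresh CATG, so iterate until none remains
      repeat {
        pos <- .last_tag_site(seqs[i])
        if (is.na(pos)) break
        substr(seqs[i], pos + 3L, pos + 3L) <- sample(c("A", "C", "T"), 1)
      }
    }
  }
  names(seqs) <- sprintf("gene_%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
  Biostrings::DNAStringSet(seqs)
}

# position (1-based) of the 3'-most CATG with >= 17 downstream bases, NA if
# none; falls back automatically to upstream sites because it takes the max
# over all qualifying anchors
.last_tag_site <- function(seq) {
  hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  ok <- hits[hits + 20L <= nchar(seq)]
  if (length(ok) == 0) NA_integer_ else max(ok)
}

#' Canonical simulated tag per gene
#'
#' The 21-nt tag an NlaIII-anchored protocol would emit for each transcript:
#' the 3'-most CATG with at least 17 downstream bases plus those 17 bases,
#' on the sense strand. Genes without a qualifying site get `NA`
#' (unrepresentable).
#'
#' @param reference a `DNAStringSet` or named character vector of transcripts.
#' @return named character vector of 21-nt tags (NA where unrepresentable).
#' @export
canonical_tags <- function(reference) {
  seqs <- .as_ref_character(reference)
  pos <- vapply(seqs, .last_tag_site, integer(1))
  tags <- ifelse(is.na(pos), NA_character_, substr(seqs, pos, pos + 20L))
  names(tags) <- names(seqs)
  tags
}

.as_ref_character <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    s <- as.character(reference)
  } else if (is.character(reference)) {
    s <- toupper(reference)
  } else .stopf("reference must be a DNAStringSet or named character vector")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    .stopf("reference sequences must have unique names")
  s
}

#' Simulate one tag library
#'
#' Draws a tag count for every profiled gene, emits that many copies of the
#' gene's canonical 21-nt tag, and corrupts each copy with independent
#' per-base substitution errors at the design's error rate. Genes without an
#' extractable tag site emit nothing and are recorded in the
#' `unrepresentable` attribute.
#'
#' @param reference transcript set (see [make_reference()]).
#' @param expression_profile named numeric vector of expected tag counts per
#'   gene; every name must exist in the reference.
#' @param design a [synth_design()]; supplies dispersion, error rate and the
#'   master seed from which this library's seed is derived.
#' @param library_id label; also keys the derived RNG stream.
#' @param noise `"auto"` (negative binomial, degrading to Poisson when the
#'   design dispersion is 0), `"nb"`, `"poisson"`, or `"fixed"` (counts equal
#'   to the rounded expected value -- the noiseless limit used in tests).
#' @return a `raw_tag_library`: list with `library_id` and `tags`, a
#'   data.frame of (tag, count). Attributes `n_copies`, `n_mutated` (ground
#'   truth for error accounting) and `unrepresentable` are attached.
#' @export
simulate_library <- function(reference, expression_profile, design, library_id,
                             noise = c("auto", "nb", "poisson", "fixed")) {
  noise <- match.arg(noise)
  seqs <- .as_ref_character(reference)
  unknown <- setdiff(names(expression_profile), names(seqs))
  if (length(unknown) > 0)
    .stopf("unknown gene id(s) in expression profile: %s",
           paste(utils::head(unknown, 3), collapse = ", "))
  if (any(expression_profile < 0)) .stopf("expected counts must be >= 0")

  set.seed(derive_seed(design$seed, paste0("lib:", library_id)))
  tags <- canonical_tags(seqs[names(expression_profile)])
  representable <- !is.na(tags)
  mu <- expression_profile[representable]
  tag_of <- tags[representable]

  if (noise == "auto") noise <- if (design$dispersion > 0) "nb" else "poisson"
  counts <- switch(noise,
    nb = stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
    poisson = stats::rpois(length(mu), mu),
    fixed = round(mu))
  copies <- rep(tag_of, counts)
  n_mutated <- 0L
  if (design$error_rate > 0 && length(copies) > 0) {
    copies <- .mutate_tags(copies, design$error_rate)
    n_mutated <- attr(copies, "n_mutated")
  }
  tab <- if (length(copies) > 0) table(copies) else table(character(0))
  out <- structure(list(
    library_id = library_id,
    tags = data.frame(tag = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  ), class = "raw_tag_library")
  attr(out, "n_copies") <- length(copies)
  attr(out, "n_mutated") <- as.integer(n_mutated)
  attr(out, "unrepresentable") <- names(expression_profile)[!representable]
  out
}

# independently substitute each base of each 21-nt copy with prob `rate`;
# vectorised over the dominant single-error case
.mutate_tags <- function(copies, rate) {
  n <- length(copies)
  nerr <- stats::rbinom(n, 21L, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  one <- hit[nerr[hit] == 1L]
  if (length(one) > 0) {
    pos <- sample.int(21L, length(one), replace = TRUE)
    cur <- match(substr(copies[one], pos, pos), bases)
    new <- ((cur - 1L + sample.int(3L, length(one), replace = TRUE)) %% 4L) + 1L
    x <- copies[one]
    substr(x, pos, pos) <- bases[new]
    copies[one] <- x
  }
  multi <- hit[nerr[hit] > 1L]
  for (i in multi) {
    pos <- sample.int(21L, nerr[i])
    x <- copies[i]
    for (p in pos) {
      cur <- match(substr(x, p, p), bases)
      substr(x, p, p) <- bases[((cur - 1L + sample.int(3L, 1)) %% 4L) + 1L]
    }
    copies[i] <- x
  }
  attr(copies, "n_mutated") <- length(hit)
  copies
}

#' Generate a synthetic gene-to-term annotation map
#'
#' Random term memberships over the reference genes, optionally with one
#' designated term forced to overlap a given gene set at a requested rate --
#' the construction used to plant a truly enriched term for testing
#' over-representation analysis.
#'
#' @param reference transcript set or character vector of gene ids.
#' @param n_terms number of terms (>= 1).
#' @param genes_per_term integer vector `c(min, max)` term size range.
#' @param seed RNG seed.
#' @param forced_term optional list `list(term_id =, genes =)` naming one
#'   term and the exact gene set it must annotate.
#' @return data.frame with columns `gene_id`, `term_id` (TSV-writable).
#' @export
make_annotation <- function(reference, n_terms, genes_per_term = c(5, 50),
                            seed = 1L, forced_term = NULL) {
  if (n_terms < 1) .stopf("n_terms must be >= 1")
  gene_ids <- if (is.character(reference) && is.null(names(reference)))
    reference else names(.as_ref_character(reference))
  set.seed(seed)
  sizes <- sample(genes_per_term[1]:genes_per_term[2], n_terms, replace = TRUE)
  sizes <- pmin(sizes, length(gene_ids))
  rows <- lapply(seq_len(n_terms), function(i) {
    data.frame(gene_id = sample(gene_ids, sizes[i]),
               term_id = sprintf("TERM_%03d", i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(forced_term)) {
    out <- out[out$term_id != forced_term$term_id, , drop = FALSE]
    out <- rbind(out, data.frame(gene_id = forced_term$genes,
                                 term_id = forced_term$term_id,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a full multi-library experiment with known ground truth
#'
#' Builds a reference, plants six temporal expression patterns across the
#' design's stages, plants differential expression between each
#' non-recipient genotype and the recipient at each stage, and simulates one
#' raw tag library per genotype-stage combination.
#'
#' Baseline abundances are log-normal; each gene's stage profile is scaled
#' by its planted cluster's pattern; DE genes get a 2^(+/- effect) multiplier
#' in the affected genotype-stage library. Ground truth records every
#' planted DE gene (contrast, direction, true log2 fold change) and every
#' gene's planted cluster.
#'
#' @param design a [synth_design()].
#' @param length_range,catg_fraction forwarded to [make_reference()].
#' @param n_clusters number of planted temporal patterns (default 6).
#' @param noise forwarded to [simulate_library()].
#' @return list with elements `reference`, `design`, `profiles` (gene x
#'   library expected counts), `libraries` (named list of raw libraries),
#'   `metadata` (library_id/genotype/stage data.frame), and `truth`
#'   (`de_genes`: named list of data.frames per contrast; `cluster_labels`).
#' @export
simulate_experiment <- function(design, length_range = c(200, 1200),
                                catg_fraction = 0.97, n_clusters = 6,
                                noise = "auto") {
  stopifnot(inherits(design, "synth_design"))
  reference <- make_reference(design$n_genes, length_range, catg_fraction,
                              seed = derive_seed(design$seed, "reference"))
  gene_ids <- names(reference)
  n <- length(gene_ids)
  n_stage <- length(design$stage_ids)

  set.seed(derive_seed(design$seed, "profiles"))
  base <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  cluster_labels <- sample(rep_len(seq_len(n_clusters), n))
  patterns <- .temporal_patterns(n_clusters, n_stage)

  # expected relative abundance per gene and stage (before DE planting)
  rel <- base * patterns[cluster_labels, , drop = FALSE]

  metadata <- expand.grid(stage = design$stage_ids,
                          genotype = design$genotype_ids,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metadata <- metadata[, c("genotype", "stage")]
  metadata$library_id <- paste(metadata$genotype, metadata$stage, sep = "_")

  profiles <- matrix(0, n, nrow(metadata),
                     dimnames = list(gene_ids, metadata$library_id))
  de_genes <- list()
  recipient <- design$genotype_ids[1]
  n_de <- round(n * design$de_fraction)
  for (j in seq_len(nrow(metadata))) {
    st <- match(metadata$stage[j], design$stage_ids)
    lam <- rel[, st]
    if (metadata$genotype[j] != recipient && n_de > 0) {
      contrast <- paste0(metadata$genotype[j], ":", metadata$stage[j], "_vs_",
                         recipient)
      idx <- sample.int(n, n_de)
      dirs <- rep(c("up", "down"), length.out = n_de)
      fc <- ifelse(dirs == "up", design$de_log2_effect, -design$de_log2_effect)
      lam[idx] <- lam[idx] * 2^fc
      de_genes[[contrast]] <- data.frame(gene_id = gene_ids[idx],
                                         direction = dirs, true_log2fc = fc,
                                         stringsAsFactors = FALSE)
    }
    profiles[, j] <- lam / sum(lam) * design$library_depth
  }

  libraries <- lapply(metadata$library_id, function(id)
    simulate_library(reference, profiles[, id], design, id, noise = noise))
  names(libraries) <- metadata$library_id

  list(reference = reference, design = design, profiles = profiles,
       libraries = libraries, metadata = metadata,
       truth = list(de_genes = de_genes,
                    cluster_labels = stats::setNames(cluster_labels, gene_ids)))
}

# linear-scale stage multipliers for planted temporal patterns; rows are
# patterns like high-early, high-late, peaked, dipped ...
.temporal_patterns <- function(k, n_stage) {
  anchor <- rbind(
    c(4, 4, 1),   # high early+mid
    c(4, 1, 1),   # high early only
    c(1, 4, 4),   # high mid+late
    c(1, 1, 4),   # high late only
    c(1, 4, 1),   # peaked mid
    c(4, 1, 4))   # dipped mid
  pat <- anchor[rep_len(seq_len(nrow(anchor)), k), , drop = FALSE]
  if (n_stage == 3) return(pat)
  # interpolate the 3-point archetypes onto the requested stage count
  t(apply(pat, 1, function(p)
    stats::approx(seq(0, 1, length.out = 3), p,
                  xout = seq(0, 1, length.out = n_stage))$y))
}

#' Write ground truth to JSON
#' @param truth the `truth` element of [simulate_experiment()].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
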