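# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive and share no code with the implementation paths they
# check.

# Benjamini-Hochberg step-up by the definition: q_i is the minimum of
# m * p_(j) / rank(j) over all sorted p_(j) >= p_i, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(m), function(j) m * sp[j] / j, numeric(1))
    min(1, min(cand[sp >= pi - 1e-15]))
  }, numeric(1))
}

# two-sided conditional binomial p-value by explicit enumeration of all
# splits of n = x + y, pmf from choose() products (independent of pbinom)
oracle_exact_test <- function(x, y, n1, n2) {
  n <- x + y
  p2 <- n2 / (n1 + n2)
  pmf <- vapply(0:n, function(k) choose(n, k) * p2^k * (1 - p2)^(n - k),
                numeric(1))
  lower <- sum(pmf[seq_len(y + 1)])          # P(Y <= y)
  upper <- sum(pmf[(y + 1):(n + 1)])          # P(Y >= y)
  min(1, 2 * min(lower, upper))
}

# upper-tail hypergeometric by exhaustive summation of the pmf written out
# with binomial coefficients
oracle_hyper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# all-pairs Hamming tag mapper: exact matches first; only tags without an
# exact hit get 1-mismatch matches, and the mismatch must sit outside the
# 4-base CATG anchor
oracle_map <- function(tags, counts, entries, max_mismatch = 1) {
  keys <- unique(entries$tag)
  genes_of_key <- lapply(keys, function(k)
    unique(entries$gene_id[entries$tag == k]))
  key_chars <- strsplit(keys, "")
  gene_counts <- list()
  ambiguous <- unmapped <- 0L
  for (i in seq_along(tags)) {
    tc <- strsplit(tags[i], "")[[1]]
    mism <- vapply(key_chars, function(kc) sum(kc != tc), integer(1))
    hit <- which(mism == 0)
    if (length(hit) == 0 && max_mismatch == 1) {
      cand <- which(mism == 1)
      # the single differing position must lie outside the anchor
      ok <- vapply(cand, function(j)
        all(which(key_chars[[j]] != tc) > 4), logical(1))
      hit <- cand[ok]
    }
    genes <- unique(unlist(genes_of_key[hit]))
    if (length(genes) == 0) unmapped <- unmapped + 1L
    else if (length(genes) > 1) ambiguous <- ambiguous + 1L
    else gene_counts[[genes]] <- (gene_counts[[genes]] %||% 0) + counts[i]
  }
  list(gene_counts = unlist(gene_counts) %||% stats::setNames(numeric(0), character(0)),
       ambiguous_distinct = ambiguous, unmapped_distinct = unmapped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive O(n^3) agglomerative clustering on a precomputed distance matrix;
# returns merge heights in order
oracle_linkage <- function(D, linkage = "average") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    ds <- D[a, b, drop = FALSE]
    if (linkage == "average") mean(ds) else max(ds)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# count transcripts carrying an extractable tag (CATG with >= 17 bases
# after it) by a regex scan of FASTA text
oracle_taggable_fraction <- function(fasta_path) {
  lines <- readLines(fasta_path)
  idx <- grepl("^>", lines)
  seqs <- tapply(lines[!idx], cumsum(idx)[!idx], paste, collapse = "")
  has_tag <- vapply(seqs, function(s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    any(hits != -1 & hits + 20 <= nchar(s))
  }, logical(1))
  mean(has_tag)
}

# small deterministic reference fixture used across mapping tests
fixture_reference <- function(n_genes = 50, len = 300, seed = 42) {
  tagdge::make_reference(n_genes, c(len, len), catg_fraction = 1, seed = seed)
}

# random raw tag pool: mixture of index-derived tags, mutated tags and junk
fixture_raw_tags <- function(index, n_distinct = 500, seed = 9) {
  set.seed(seed)
  keys <- index$keys
  picks <- sample(keys, n_distinct, replace = TRUE)
  mutate <- stats::runif(n_distinct) < 0.3
  pos <- sample(1:21, n_distinct, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (i in which(mutate)) {
    cur <- substr(picks[i], pos[i], pos[i])
    substr(picks[i], pos[i], pos[i]) <- sample(setdiff(bases, cur), 1)
  }
  agg <- stats::aggregate(
    count ~ tag,
    data.frame(tag = picks, count = sample(2:50, n_distinct, replace = TRUE)),
    sum)
  structure(list(library_id = "fixture", tags = agg), class = "raw_tag_library")
}
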