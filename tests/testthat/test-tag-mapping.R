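test_that("clean_tags applies the three stated filters", {
  raw <- data.frame(tag = c("CATGAAAAAAAAAAAAAAAAA", "CATGCCC"),
                    count = c(5L, 3L))
  cl <- clean_tags(raw)
  expect_equal(cl$clean_tags$tag, "CATGAAAAAAAAAAAAAAAAA")
  expect_equal(cl$raw_total, 8L)
  expect_equal(cl$clean_total, 5L)

  # singletons are removed
  cl2 <- clean_tags(data.frame(tag = "CATGAAAAAAAAAAAAAAAAA", count = 1L))
  expect_equal(cl2$distinct_clean, 0L)
  expect_equal(cl2$clean_total, 0L)

  # N-containing tags are removed
  cl3 <- clean_tags(data.frame(tag = paste0("CATGN", strrep("A", 16)),
                               count = 9L))
  expect_equal(cl3$distinct_clean, 0L)
  expect_error(clean_tags(data.frame(tag = "CATG-bad", count = 2L)), "ACGTN")
})

test_that("clean accounting matches an independent refilter on a random pool", {
  set.seed(31)
  n <- 1e4
  lens <- sample(c(18L, 21L, 21L, 21L), n, replace = TRUE)
  tags <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
    character(1))
  counts <- ifelse(stats::runif(n) < 0.3, 1L,
                   sample(2:30, n, replace = TRUE))
  pool <- stats::aggregate(count ~ tag, data.frame(tag = tags, count = counts),
                           sum)
  cl <- clean_tags(pool)
  keep <- nchar(pool$tag) == 21 & !grepl("N", pool$tag) & pool$count >= 2
  expect_equal(cl$clean_total, sum(pool$count[keep]))
  expect_equal(cl$distinct_clean, sum(keep))
  expect_lte(cl$clean_total, cl$raw_total)
  expect_lte(cl$distinct_clean, cl$distinct_raw)
  expect_equal(cl$clean_total, sum(cl$clean_tags$count))
})

test_that("exact unique hits and multi-gene exclusion behave as stated", {
  key <- "CATGAAAAAAAAAAAAAAAAA"
  idx <- build_index(c(g1 = key))
  cl <- clean_tags(data.frame(tag = key, count = 7L))
  mp <- map_library(cl, idx)
  expect_equal(mp$gene_counts, c(g1 = 7))
  expect_equal(mp$ambiguous_distinct, 0L)
  expect_equal(mp$genes_hit, 1L)

  # same tag in two genes -> ambiguous, contributes to no gene
  idx2 <- build_index(c(g1 = key, g2 = paste0("TTTT", key)))
  mp2 <- map_library(cl, idx2)
  expect_equal(mp2$ambiguous_distinct, 1L)
  expect_length(mp2$gene_counts, 0L)
  expect_equal(mp2$mapped_clean_total, 0)

  # two positions within ONE gene are fine and summed
  one_gene <- paste0(key, strrep("G", 5), key)
  idx3 <- build_index(c(g1 = one_gene))
  mp3 <- map_library(cl, idx3)
  expect_equal(mp3$gene_counts, c(g1 = 7))

  bad <- list(library_id = "x", clean_tags = data.frame(tag = "CATGAA",
                                                        count = 2L))
  expect_error(map_library(bad, idx), "21 nt")
})

test_that("one-mismatch search honors the anchor and exact-match priority", {
  key <- "CATGAAAAAAAAAAAAAAAAA"
  idx <- build_index(c(g1 = key))
  variant <- key
  substr(variant, 10, 10) <- "G"
  cl <- clean_tags(data.frame(tag = variant, count = 4L))
  expect_equal(map_library(cl, idx, max_mismatch = 1)$gene_counts, c(g1 = 4))
  expect_equal(map_library(cl, idx, max_mismatch = 0)$unmapped_distinct, 1L)

  # a mismatch inside the CATG anchor is not allowed
  anchor_var <- key
  substr(anchor_var, 2, 2) <- "G"
  cl2 <- clean_tags(data.frame(tag = anchor_var, count = 4L))
  expect_equal(map_library(cl2, idx, max_mismatch = 1)$unmapped_distinct, 1L)

  # exact-match priority: a tag that IS a key maps to that key's gene even
  # if its 1-mismatch neighborhood reaches a second gene
  key2 <- key
  substr(key2, 21, 21) <- "T"
  idx2 <- build_index(c(g1 = key, g2 = paste0("CC", key2)))
  cl3 <- clean_tags(data.frame(tag = key, count = 3L))
  mp <- map_library(cl3, idx2, max_mismatch = 1)
  expect_equal(mp$gene_counts, c(g1 = 3))
  expect_equal(mp$ambiguous_distinct, 0L)
})

test_that("mapping agrees with the all-pairs Hamming oracle", {
  ref <- fixture_reference(50, len = 250, seed = 17)
  idx <- build_index(ref)
  raw <- fixture_raw_tags(idx, n_distinct = 500, seed = 23)
  cl <- clean_tags(raw)
  for (mm in c(0, 1)) {
    mp <- map_library(cl, idx, max_mismatch = mm)
    orc <- oracle_map(cl$clean_tags$tag, cl$clean_tags$count, idx$entries, mm)
    expect_equal(mp$gene_counts[sort(names(mp$gene_counts))],
                 orc$gene_counts[sort(names(orc$gene_counts))])
    expect_equal(mp$ambiguous_distinct, orc$ambiguous_distinct)
    expect_equal(mp$unmapped_distinct, orc$unmapped_distinct)
  }
})

test_that("mapping invariants hold on simulated libraries", {
  ref <- fixture_reference(80, seed = 29)
  idx <- build_index(ref)
  des0 <- synth_design(n_genes = 80, library_depth = 4000, error_rate = 0,
                       seed = 6)
  prof <- stats::setNames(rep(50, 80), names(ref))
  lib0 <- simulate_library(ref, prof, des0, "E0")
  cl0 <- clean_tags(lib0)
  mp0 <- map_library(cl0, idx, max_mismatch = 0)
  # error-free canonical tags: nothing unmapped; ambiguity only from shared tags
  expect_equal(mp0$unmapped_distinct, 0L)
  # raising the mismatch allowance changes nothing when all tags hit exactly
  mp1 <- map_library(cl0, idx, max_mismatch = 1)
  expect_equal(mp1$gene_counts, mp0$gene_counts)

  desE <- synth_design(n_genes = 80, library_depth = 4000, error_rate = 0.03,
                       seed = 6)
  libE <- simulate_library(ref, prof, desE, "E1")
  clE <- clean_tags(libE)
  mpE0 <- map_library(clE, idx, max_mismatch = 0)
  mpE1 <- map_library(clE, idx, max_mismatch = 1)
  expect_gte(mpE1$mapped_clean_total, mpE0$mapped_clean_total)
  # accounting identity on both
  for (m in list(mpE0, mpE1))
    expect_equal(m$distinct_mapped + m$ambiguous_distinct + m$unmapped_distinct,
                 clE$distinct_clean)
})

test_that("gene_expression produces TPM that conserves 1e6", {
  mk <- function(counts, total) structure(
    list(library_id = "L", gene_counts = counts, mapped_clean_total = total),
    class = "mapping_result")
  expect_equal(gene_expression(mk(c(g1 = 50, g2 = 50), 100)),
               c(g1 = 5e5, g2 = 5e5))
  expect_equal(gene_expression(mk(c(g1 = 1), 1e6)), c(g1 = 1))
  expect_error(gene_expression(mk(stats::setNames(numeric(0), character(0)), 0)),
               "zero mapped")

  ref <- fixture_reference(40, seed = 33)
  idx <- build_index(ref)
  des <- synth_design(n_genes = 40, library_depth = 3000, error_rate = 0.01,
                      seed = 2)
  lib <- simulate_library(ref, stats::setNames(rep(75, 40), names(ref)), des, "T")
  mp <- map_library(clean_tags(lib), idx)
  expect_equal(sum(gene_expression(mp)), 1e6, tolerance = 1e-6)
})

test_that("library_qc validates inputs and rounds half-up to 2 decimals", {
  expect_error(library_qc(list(clean_total = 1), list(), 0), "n_reference_genes")
  qc <- library_qc(
    list(library_id = "L", raw_total = 100, distinct_raw = 60,
         clean_total = 80, distinct_clean = 40),
    list(library_id = "L", mapped_clean_total = 20, distinct_mapped = 10,
         genes_hit = 3),
    n_reference_genes = 7)
  expect_equal(qc$pct_clean_mapped, 25)
  expect_equal(qc$pct_distinct_mapped, 25)
  expect_equal(qc$pct_reference_genes, 42.86)  # 3/7 = 42.857...
  expect_error(
    library_qc(list(library_id = "A", clean_total = 1),
               list(library_id = "B", mapped_clean_total = 1), 10),
    "disagree")
})

test_that("tag files round-trip in both plain-text layouts", {
  lib <- structure(list(
    library_id = "rt",
    tags = data.frame(tag = c("CATGAAAAAAAAAAAAAAAAA", "CATGCCCCCCCCCCCCCCCCC"),
                      count = c(3L, 2L))), class = "raw_tag_library")
  f <- tempfile(fileext = ".tsv")
  write_tag_file(lib, f)
  back <- read_tag_file(f, "rt")
  expect_equal(back$tags[order(back$tags$tag), ],
               lib$tags[order(lib$tags$tag), ], ignore_attr = TRUE)

  f2 <- tempfile(fileext = ".txt")
  writeLines(rep(lib$tags$tag, lib$tags$count), f2)
  back2 <- read_tag_file(f2)
  expect_equal(back2$tags[order(back2$tags$tag), ]$count, c(3L, 2L))
})
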