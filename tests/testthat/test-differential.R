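test_that("exact_tag_test: boundary cases and sign conventions", {
  expect_equal(exact_tag_test(0, 0, 1e6, 1e6), 1)
  expect_equal(exact_tag_test(5, 5, 1e6, 1e6), 1)
  expect_equal(exact_tag_test(0, 20, 1e6, 1e6), 2 * 0.5^20,
               tolerance = 1e-12)
  expect_error(exact_tag_test(-1, 0, 10, 10), "non-negative")
  expect_error(exact_tag_test(1, 1, 0, 10), "positive")
})

test_that("exact_tag_test is symmetric under swapping the two libraries", {
  set.seed(53)
  for (i in 1:50) {
    x <- rpois(1, 30); y <- rpois(1, 60)
    n1 <- sample(1e5:1e6, 1); n2 <- sample(1e5:1e6, 1)
    expect_equal(exact_tag_test(x, y, n1, n2), exact_tag_test(y, x, n2, n1),
                 tolerance = 1e-12)
  }
})

test_that("exact_tag_test matches full enumeration for all x+y <= 50", {
  for (totals in list(c(1e6, 1e6), c(8144920, 7013147), c(5e4, 2e5))) {
    for (n in c(0:10, 20, 35, 50)) {
      for (y in 0:n) {
        got <- exact_tag_test(n - y, y, totals[1], totals[2])
        want <- oracle_exact_test(n - y, y, totals[1], totals[2])
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("bh_adjust: trivial and hand-derived cases", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the brute-force step-up oracle and is monotone", {
  set.seed(59)
  for (i in 1:100) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("call_degs applies inclusive thresholds and counts directions", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2_ratio = c(1.0, 5, -2, 0.5),
                    p_value = c(0.0005, 0.002, 0.0001, 0.0001) / 4)
  # craft p so that BH q-values land exactly where we want: use a single
  # record per comparison instead for exact boundary control
  one <- function(p, lr) call_degs(data.frame(gene_id = "g", log2_ratio = lr,
                                              p_value = p))
  expect_true(one(0.0005, 1.0)$records$is_deg)    # both boundaries inclusive
  expect_true(one(0.001, -1.0)$records$is_deg)
  expect_false(one(0.002, 5)$records$is_deg)      # fails the FDR gate
  expect_false(one(0.0005, 0.99)$records$is_deg)  # fails the ratio gate
  cmp <- call_degs(rec)
  expect_equal(cmp$n_up + cmp$n_down, sum(cmp$records$is_deg))
  expect_equal(cmp$records$direction,
               ifelse(cmp$records$log2_ratio > 0, "up", "down"))
})

test_that("null simulated libraries stay super-uniform and rarely called", {
  # small version of the calibration check; the full 20-seed run lives in
  # the acceptance suite
  set.seed(61)
  n_genes <- 2000
  hits <- 0; tested <- 0; p_at_05 <- numeric(0)
  for (s in 1:3) {
    lam <- rep(100, n_genes)
    x <- rpois(n_genes, lam); y <- rpois(n_genes, lam)
    p <- exact_tag_test(x, y, sum(x), sum(y))
    p_at_05 <- c(p_at_05, mean(p <= 0.05))
    q <- bh_adjust(p)
    tpm_x <- 1e6 * x / sum(x); tpm_y <- 1e6 * y / sum(y)
    lr <- log2((tpm_y + 0.5) / (tpm_x + 0.5))
    hits <- hits + sum(q <= 0.001 & abs(lr) >= 1)
    tested <- tested + n_genes
  }
  expect_lte(mean(p_at_05), 0.075)
  expect_lte(hits / tested, 0.005)
})

test_that("common_degs partitions Venn regions correctly", {
  mk_cmp <- function(label, genes, dirs) structure(list(
    label = label,
    records = data.frame(gene_id = genes, is_deg = TRUE, direction = dirs,
                         log2_ratio = ifelse(dirs == "up", 2, -2)),
    n_up = sum(dirs == "up"), n_down = sum(dirs == "down")),
    class = "dge_comparison")

  a <- mk_cmp("A", c("g1", "g2"), c("up", "down"))
  cd_same <- common_degs(list(A = a, B = a))
  expect_setequal(cd_same$common, c("g1", "g2"))

  b <- mk_cmp("B", c("g3", "g4"), c("up", "up"))
  cd_disj <- common_degs(list(A = a, B = b))
  expect_length(cd_disj$common, 0L)
  expect_setequal(names(cd_disj$regions), c("A", "B"))

  # direction-restricted intersection
  c2 <- mk_cmp("C", c("g1", "g2"), c("up", "up"))
  up <- common_degs(list(A = a, C = c2), mode = "same_direction_up")
  expect_equal(up$common, "g1")

  expect_error(common_degs(list(A = a)), "two comparisons")
})

test_that("common_degs region sizes match a membership-vector oracle", {
  set.seed(67)
  genes <- sprintf("g%03d", 1:200)
  sets <- lapply(1:3, function(i) sample(genes, 60))
  cmps <- lapply(1:3, function(i) structure(list(
    label = LETTERS[i],
    records = data.frame(gene_id = sets[[i]], is_deg = TRUE,
                         direction = "up", log2_ratio = 2)),
    class = "dge_comparison"))
  names(cmps) <- LETTERS[1:3]
  cd <- common_degs(cmps)
  u <- unique(unlist(sets))
  member <- sapply(sets, function(s) u %in% s)
  pat <- apply(member, 1, function(m) paste(LETTERS[1:3][m], collapse = "&"))
  expect_equal(cd$sizes[sort(names(cd$sizes))],
               vapply(split(u, pat), length, integer(1))[sort(unique(pat))])
})

test_that("relative_expression follows the 2^-dCt convention", {
  expect_equal(relative_expression(0), 1)
  expect_equal(relative_expression(1), 0.5)
  expect_equal(relative_expression(-2), 4)
})

test_that("compare_libraries produces a coherent table end to end", {
  set.seed(71)
  counts_a <- c(g1 = 100, g2 = 400, g3 = 50)
  counts_b <- c(g1 = 100, g2 = 100, g3 = 240)
  mk <- function(id, gc) structure(
    list(library_id = id, gene_counts = gc, mapped_clean_total = 1e5),
    class = "mapping_result")
  m <- assemble(list(mk("A", counts_a), mk("B", counts_b)))
  cmp <- compare_libraries(m, "A", "B")
  r <- cmp$records
  expect_equal(r$q_value, bh_adjust(r$p_value))
  expect_true(all(r$q_value >= r$p_value - 1e-15))
  expect_true(r$is_deg[r$gene_id == "g2"])  # 4-fold down, large counts
  expect_equal(r$direction[r$gene_id == "g2"], "down")
  f <- tempfile(fileext = ".tsv")
  write_comparison_tsv(cmp, f)
  expect_equal(utils::read.delim(f)$gene_id, r$gene_id)
})
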