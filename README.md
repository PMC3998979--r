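# tagdge

Tag-based digital gene expression (DGE) profiling in R: the classical
NlaIII/CATG 21-bp tag-seq analysis chain, reimplemented as a tested,
reusable package with a synthetic-data generator so every stage can be
validated against known ground truth without any external download.

**Who it is for:** anyone analyzing restriction-anchored tag count
libraries (one library per condition, no replicates) — or teaching /
auditing that analysis style — who wants each step to be an inspectable,
unit-tested function rather than a vendor pipeline.

## What it computes

* **Tag database** — every 21-base window starting at a CATG anchor with
  ≥ 17 downstream bases, indexed by sequence with (gene, offset, strand)
  occurrences (`build_index`).
* **Cleaning & mapping** — drop short/N/singleton tags; map with at most
  one mismatch (never inside the anchor), exclude tags matching more than
  one gene, sum per-gene counts (`clean_tags`, `map_library`).
* **Quantification** — TPM(g) = 10⁶ · count(g) / mapped total
  (`gene_expression`, `assemble`).
* **Differential expression** — exact conditional two-library count test:
  with library totals N₁, N₂ and gene counts x, y, under the null
  y | x+y ~ Binomial(x+y, N₂/(N₁+N₂)); two-sided p = min(1, 2·min(tails)),
  Benjamini–Hochberg q within each comparison, DEG ⇔ q ≤ 0.001 and
  |log₂ ratio| ≥ 1 (`exact_tag_test`, `bh_adjust`, `compare_libraries`).
* **Clustering** — from-scratch SOTA (self-organizing tree algorithm) and
  hierarchical clustering with k-group cuts on log₂(TPM + 1) profiles
  (`sota_cluster`, `hier_cluster`).
* **Enrichment** — one-sided hypergeometric over-representation with BH
  correction and the ratio column 100·k/K (`enrich`).
* **Synthetic data** — seeded generator for reference transcriptomes, tag
  libraries with per-base sequencing error, annotation maps, planted DE
  and planted temporal clusters (`make_reference`, `simulate_library`,
  `simulate_experiment`, `make_annotation`).
* **Pipeline** — configuration-driven end-to-end driver with a manifest
  and byte-reproducible outputs (`run_pipeline`, `tagdge_cli`).

## Worked example

```r
library(tagdge)
des <- synth_design(n_genes = 300, genotype_ids = c("TM1", "IL1"),
                    library_depth = 3e4, de_fraction = 0.1,
                    de_log2_effect = 2, seed = 42)
sim <- simulate_experiment(des)
idx <- build_index(sim$reference)
print(idx)
#> CATG tag index: 815 distinct tags, 815 positions, 291 of 300 genes represented

cl  <- lapply(sim$libraries, clean_tags)
mp  <- lapply(cl, map_library, index = idx)
qc  <- library_qc(cl$TM1_15DPA, mp$TM1_15DPA, length(sim$reference))
#> TM1_15DPA: 26302 clean tags, 98.14% mapped, 282 genes (94.00% of reference)

mat <- assemble(unname(mp), sim$metadata)
cmp <- compare_libraries(mat, "TM1_15DPA", "IL1_15DPA")
print(cmp)
#> IL1_15DPA_vs_TM1_15DPA: 284 genes tested, 20 DEGs (12 up, 8 down)

truth <- sim$truth$de_genes[["IL1:15DPA_vs_TM1"]]
mean(truth$gene_id %in% deg_set(cmp))
#> [1] 0.667
```

Reading the numbers: 291 of 300 simulated transcripts carry an extractable
CATG tag (the 97% default); 98.14% of the TM1 15-DPA library's clean tags
map uniquely, hitting 94% of the reference. The 15-DPA contrast calls 20
DEGs at FDR ≤ 0.001, |log₂ ratio| ≥ 1. Sensitivity against the planted
truth is 0.667 at this deliberately small smoke depth (3 × 10⁴ tags):
planted DE genes drawn from the log-normal low-abundance tail have too few
tags to reach significance. At the realistic scaled depth used by the
acceptance suite (2 × 10⁵ tags, mean count ≈ 100/gene) sensitivity
exceeds 0.9 while the null DEG rate stays below 0.5%.

Full pipeline in one call (artifacts + manifest written as plain text):

```r
run_pipeline(default_config(seed = 1), out_dir = "tagdge_out")
```

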