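---
title: "Methods and design notes for tag-based DGE analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for tag-based DGE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The analysis this package implements

Restriction-anchored tag sequencing ("tag-seq" / DGE profiling) measures
transcript abundance by counting short sequence tags instead of full reads.
An anchoring enzyme (NlaIII, recognition site CATG) cuts each cDNA; the
protocol releases a 21-base tag consisting of the CATG site plus the 17
bases downstream of the 3'-most site, and the tag count is a digital
estimate of the transcript's abundance. The classical analysis chain is:

1. **Tag database.** Every 21-base window starting at a CATG in the
   reference transcript set becomes a database key mapping to
   (gene, offset, strand) occurrences.
2. **Cleaning.** Raw tags shorter than 21 nt, containing ambiguous bases,
   or seen only once in a library (singletons) are discarded.
3. **Mapping.** Each clean tag is matched against the database allowing at
   most one mismatch; tags matching more than one gene are excluded as
   ambiguous. Counts mapped to different positions of the same gene are
   summed.
4. **Quantification.** Per-gene counts are scaled to transcripts per
   million: `TPM(g) = 1e6 * count(g) / mapped_total`.
5. **Differential expression.** For each pair of libraries, an exact
   conditional count test per gene, Benjamini–Hochberg FDR within the
   comparison, and the thresholds `FDR <= 0.001` with `|log2 ratio| >= 1`.
6. **Clustering.** Log2 TPM profiles of genes expressed in at least three
   libraries of one developmental stage, grouped by SOTA (self-organizing
   tree algorithm) or agglomerative hierarchical clustering.
7. **Enrichment.** Hypergeometric over-representation of gene sets against
   a gene-to-term annotation, with the per-term ratio `100 * k / K`
   conventionally printed next to pathway tables.

## The exact test

With no replicates (one library per condition, the design this method was
built for), the test conditions on the total `x + y` tags observed for a
gene across the two libraries. Under the null of equal relative abundance,
`y | x + y ~ Binomial(x + y, N2 / (N1 + N2))`, where `N1`, `N2` are the
libraries' mapped totals. We report the two-sided p-value
`min(1, 2 * min(P(Y <= y), P(Y >= y)))` — an explicit, testable convention;
it is symmetric under swapping `(x, N1)` with `(y, N2)` and equals 1 for a
perfectly balanced split. This is the Audic–Claverie-style conditional
test that was the de facto standard for two-library tag DGE; the
original analysis pipeline's precise formula is unrecorded, so the choice
is ours and the function is exposed so an alternative can be substituted.
The tail is computed through `pbinom()`'s regularized incomplete beta,
which stays within 1e-10 relative error of direct enumeration far beyond
totals of 1e4 (the test suite checks all splits with `x + y <= 50`
against an explicit enumeration oracle).

The q-value is Benjamini–Hochberg, applied *within* each comparison, not
pooled across comparisons — consistent with "per comparison" reporting.
`log2_ratio` is computed on TPM with a pseudo-TPM offset (default 0.5
added to both sides) so genes absent from one library remain reportable;
the source analysis does not state its zero handling, so the offset is a
documented knob.

## Tag mapping decisions

* **All CATG sites are indexed**, not only the 3'-most: real libraries
  contain internal-site tags from partial digestion. The simulator emits
  only the canonical (3'-most valid) site, so tests can distinguish the
  two behaviors.
* **Exact-match priority.** A tag with an exact database hit never
  receives additional 1-mismatch hits. Without this rule a sequencing
  error neighbor of a second gene's tag would inflate ambiguity. The
  source text is silent; this is our documented choice, enforced by the
  all-pairs Hamming oracle in the tests.
* **No mismatches inside the anchor.** The CATG prefix is enzymatic, not
  read-derived, so the 1-mismatch neighborhood is the 3 x 17 = 51
  substitution variants of positions 5–21.
* **Ambiguity is gene-level.** Multiple matched positions within one gene
  are fine and summed; matches spanning two or more genes disqualify the
  tag entirely.
* **Percentages** in the QC table are rounded half-up to two decimals, the
  convention under which all published table percentages in this design
  reproduce exactly from their printed numerators and denominators.
* "Low quality" beyond short tags and singletons is not further specified
  anywhere; only the three stated filters (length, N, singleton) are
  implemented.

## SOTA

The self-organizing tree algorithm is implemented from scratch: a growing
binary tree whose leaves are cluster "cells". Per growth cycle the leaf
centroids adapt online (each gene is presented in input order; the nearest
leaf wins and moves toward the gene with rate 0.01; when the winner's
sister is also a leaf, the parent and sister move with rates 0.005 and
0.001), then the leaf with the largest *resource* — mean member-to-centroid
distance — splits into two daughters initialized as jittered copies of the
parent. Growth stops at the resource threshold, the cluster budget, or the
cycle budget. These learning rates and the split criterion follow the
original algorithm description; the MeV configuration used in the source
analysis is unrecorded, so all of them are exposed as arguments.

Numerical choices:

* Distance defaults to Pearson correlation distance `1 - r`, the
  expression-profile convention; Euclidean is available.
* A constant profile is defined to be at distance 0 from another constant
  profile and 1 from any non-constant one, avoiding division by zero.
* Distances below 1e-12 are clamped to exactly 0 so floating-point noise
  in `1 - r` cannot trigger a spurious split of a homogeneous leaf.
* Daughter centroids get seeded `N(0, 1e-3)` jitter to break the symmetry
  of an exact copy; winner ties break toward the lowest node id. Given a
  seed, the fit is fully deterministic.
* A degenerate split can leave a daughter that never wins a gene; empty
  leaves stay in the tree but are not given cluster labels, and the
  cluster budget counts occupied leaves only.

Hierarchical clustering is standard agglomeration (`stats::hclust`) with
average or complete linkage on the same distances, cut at `k`; the test
suite verifies its merge heights against a naive O(n^3) agglomeration
oracle, so the dependency is used behind a checked contract.

## The synthetic world

The generator emulates the study design this pipeline was built around:
five genotypes (a recipient line plus four introgression lines) sampled at
three developmental stages (15/20/25 days post-anthesis), one library per
genotype-stage combination. Values the source states are kept: planted
DEGs use `|log2 fold change| >= 1` (default 2, the value exercised by the
recovery criteria), DEG thresholds are FDR 0.001 and ratio 1, tags are
21 nt, and 97% of reference transcripts carry an extractable tag (a
realistic figure for a CATG-anchored protocol on a eukaryotic
transcriptome; the source does not state one). Library depth defaults to
2e5 clean tags — the published libraries run 7–14 million, scaled down
~50x so the full pipeline runs in seconds while keeping mean per-gene
counts near 100. Baseline abundances are log-normal (sdlog 1.2, a typical
bulk-transcriptome spread); temporal structure comes from six planted
stage patterns (high-early, high-late, peaked, dipped, ...).

Count noise is negative-binomial with user dispersion; `dispersion = 0`
selects the Poisson limit, and a `"fixed"` noise model (counts equal to
the rounded expectation) provides the noiseless limit the unit tests pin
exact values against. Sequencing error is independent per-base
substitution (no indels — tags are fixed-length by construction), with a
per-copy corruption probability of `1 - (1 - e)^21` that the tests check
in closed form. All randomness derives from one master seed via a
documented per-stream hash, so fixtures are bit-reproducible.

The source study sequenced 14 libraries for a 5 x 3 design (which
genotype-stage cell is missing is not stated); the design object accepts
arbitrary genotype and stage subsets, and the default synthetic design
uses the full 15-cell grid.

What the generator does **not** emulate: quality scores (the pipeline
consumes base-called tags), PCR duplication, adapter artifacts, ambiguous
reference bases, and genuine biological dispersion between replicates
(the design has none). A green recovery test therefore establishes that
the pipeline is correct for the stated generative model, not that the
exact test is calibrated for overdispersed biological replicates — it is
not, and replicate-aware models (edgeR/DESeq2) are out of scope here by
design.

## Stage filter and clustering input

"Expressed in at least three libraries at one stage" is implemented as
TPM strictly greater than a threshold (default 0) in `>= min_libraries`
libraries of at least one stage; whether the original filter used a
higher floor is unstated, so the threshold is a knob. The pipeline driver
lowers `min_libraries` to the per-stage library count when a design has
fewer libraries per stage than the default of 3 (otherwise a two-genotype
smoke design would filter out every gene). The log2 transform uses a
pseudo-TPM of 1 so zero TPM maps to 0.

## Enrichment

One-sided (over-representation) hypergeometric only. The universe
defaults to the annotated genes — matching tables reported against
"reference genes with pathway annotation" — and is switchable. Whether
the original pathway table applied a significance test or only the ratio
is unstated, so both the p/q-values and the ratio are emitted. BH is
applied across terms within one query set; that correction choice is ours.

## Known limitations

* The exact test assumes Poisson sampling within a library; with planted
  negative-binomial dispersion it is anticonservative (by construction,
  not by bug).
* One-mismatch mapping cannot rescue tags whose error falls in the CATG
  anchor; those are unmappable by design.
* SOTA's online updates make the fit weakly dependent on gene input
  order; for well-separated clusters the partition is order-invariant (a
  tested property), but ties on noisy data may move individual genes.
* Published headline DEG counts from the source study are not
  reproducible by anyone — the raw libraries were never deposited — so
  correctness is anchored on in-table arithmetic and on synthetic-data
  recovery with known ground truth.
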