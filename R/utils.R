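#' Round half away from zero
#'
#' Fixed-precision rounding where ties go up (`0.125 -> 0.13` at two
#' decimals), matching how percentages are conventionally printed in DGE
#' library-statistics tables. Base R's `round()` rounds half to even, which
#' disagrees with printed tables on exact-tie values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against values like 54.245 being represented just
  # below the tie point in binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items.
#' Used to score recovery of planted cluster structure: 1 means identical
#' partitions up to label permutation, 0 is the expectation under random
#' labelling.
#'
#' @param a,b vectors of cluster labels, same length, aligned by position.
#' @return scalar ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxidx - expected)
}

# deterministic 28-bit string hash; used to derive per-library seeds from a
# master seed so that each library's randomness is independent but
# reproducible
.string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 268435456L
  h
}

# derive a 31-bit seed for a named sub-stream of a master seed
derive_seed <- function(master_seed, stream_id) {
  (as.numeric(master_seed) * 48271 + .string_hash(stream_id)) %% 2147483647
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
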