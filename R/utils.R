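# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All stochastic stages derive their own stream from one master seed so that
#' stages can be re-run independently yet reproducibly. Results stay below
#' 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param offset integer stream offset (one per stage / rerun).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects.
#' Used to score recovery of planted co-expression modules; label identities
#' are irrelevant, only the induced partition matters.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return numeric scalar in (-1, 1], 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# standardize rows of a matrix to mean 0 sd 1; zero-variance rows -> all zero
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

# genes (1-based, inclusive) overlapping segments (0-based, half-open)
# via GenomicRanges any-overlap
genes_in_segments <- function(genes, segments) {
  if (nrow(segments) == 0L || nrow(genes) == 0L) return(character(0))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  s <- GenomicRanges::GRanges(segments$chrom,
                              IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(g, s)
  unique(genes$id[S4Vectors::queryHits(hits)])
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(x < min) || any(x != floor(x)))
    stop(sprintf("'%s' must be an integer count >= %s", name, min), call. = FALSE)
  invisible(x)
}
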