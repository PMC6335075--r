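# Expression normalization, time-course differential expression and
# profile standardization.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((length/1000) * (library_size/1e6))`. The companion
#' transform used throughout downstream modules is `log2(rpkm + 1)`.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths named vector of gene lengths in bp; every row of
#'   `counts` must be covered.
#' @param library_sizes per-sample library sizes; defaults to column sums.
#' @return matrix of RPKM values with the dimensions of `counts`.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0)
    stop("missing gene length for: ", paste(utils::head(missing, 5),
                                            collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0) || any(library_sizes <= 0))
    stop("gene lengths and library sizes must be positive")
  sweep(counts / (len / 1000), 2, library_sizes / 1e6, "/")
}

#' log2(RPKM + 1)
#' @inheritParams rpkm
#' @export
log2_rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  log2(rpkm(counts, gene_lengths, library_sizes) + 1)
}

#' Expressed-gene filter
#'
#' Keeps genes reaching `min_rpkm` in at least `min_samples` samples of a
#' genotype. With `genotype = NULL` the union over genotypes is returned.
#'
#' @param expr genes x samples RPKM matrix.
#' @param samples sample sheet with `sample` and `genotype` columns.
#' @param min_rpkm,min_samples thresholds (both >= 0).
#' @param genotype restrict to one genotype, or NULL for the union.
#' @return character vector of gene ids.
#' @export
expressed_filter <- function(expr, samples, min_rpkm = 1, min_samples = 2,
                             genotype = NULL) {
  stopifnot(min_rpkm >= 0, min_samples >= 0)
  genos <- if (is.null(genotype)) unique(samples$genotype) else genotype
  keep <- rep(FALSE, nrow(expr))
  for (g in genos) {
    cols <- samples$sample[samples$genotype == g]
    keep <- keep | rowSums(expr[, cols, drop = FALSE] >= min_rpkm) >= min_samples
  }
  rownames(expr)[keep]
}

# double-tail negative-binomial exact test on group sums, conditioning on
# the total; sums of i.i.d. NB(mu, phi) replicates are NB(n*mu, phi/n)
nb_exact_p <- function(y1, y2, n1, n2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  phi <- max(phi, 1e-8)
  y <- 0:s
  lp <- stats::dnbinom(y, size = n1 / phi, mu = n1 * mu, log = TRUE) +
    stats::dnbinom(s - y, size = n2 / phi, mu = n2 * mu, log = TRUE)
  lp <- lp - logsumexp(lp)
  pobs <- lp[y1 + 1L]
  min(1, sum(exp(lp[lp <= pobs + 1e-10])))
}

#' Time-course differential expression within a genotype
#'
#' Per-gene negative-binomial exact test between two timepoints of one
#' genotype, conditioning on the gene's total count. Dispersions are
#' estimated by method of moments per gene and shrunk toward the common
#' (median) dispersion; counts are first scaled to a common library size.
#' Multiplicity is controlled by Benjamini-Hochberg; a gene is called
#' `up`/`down` iff `q < q_max` and `|log2fc| >= lfc_min`, else `ns`.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet (sample, genotype, timepoint, replicate).
#' @param genotype genotype to test within.
#' @param contrast length-2 character vector of timepoints `(a, b)`;
#'   `log2fc` is `log2(mean_b / mean_a)`.
#' @param dispersion_mode `"moderated"` (default), `"common"` or
#'   `"tagwise"`.
#' @param shrink weight of the common dispersion under `"moderated"`.
#' @param q_max,lfc_min significance rule for the direction call.
#' @return `data.table` (gene, contrast, log2fc, p, q, direction).
#' @export
de_test <- function(counts, samples, genotype, contrast,
                    dispersion_mode = c("moderated", "common", "tagwise"),
                    shrink = 0.5, q_max = 0.05, lfc_min = 1) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(length(contrast) == 2)
  geno <- genotype  # avoid column-name capture in the data.table filter
  sel <- data.table::as.data.table(samples)
  sel <- sel[sel$genotype == geno & sel$timepoint %in% contrast, ]
  for (tp in contrast)
    if (sum(sel$timepoint == tp) < 2)
      stop("contrast level '", tp, "' needs >= 2 replicates in genotype ",
           genotype)
  cols_a <- sel$sample[sel$timepoint == contrast[1]]
  cols_b <- sel$sample[sel$timepoint == contrast[2]]
  x <- counts[, c(cols_a, cols_b), drop = FALSE]

  # median-of-ratios size factors: robust to coherent (asymmetric) DE,
  # unlike total-count scaling which suffers composition bias
  lgm <- rowMeans(log(x + 0.5))
  ok_g <- is.finite(lgm)
  sf <- apply(x[ok_g, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col + 0.5) - lgm[ok_g])))
  sf <- sf / exp(mean(log(sf)))
  x_norm <- sweep(x, 2, sf, "/")
  a <- x_norm[, cols_a, drop = FALSE]
  b <- x_norm[, cols_b, drop = FALSE]
  n1 <- length(cols_a); n2 <- length(cols_b)

  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1, stats::var); v_b <- apply(b, 1, stats::var)
  pooled_var <- ((n1 - 1) * v_a + (n2 - 1) * v_b) / (n1 + n2 - 2)
  pooled_mean <- (n1 * m_a + n2 * m_b) / (n1 + n2)
  phi_raw <- (pooled_var - pooled_mean) / pooled_mean^2
  phi_raw[!is.finite(phi_raw)] <- NA
  # common dispersion from the unfloored estimates: flooring first and then
  # averaging biases the pool low and makes the exact test anti-conservative
  phi_common <- max(0, mean(phi_raw[pooled_mean >= 1], na.rm = TRUE))
  if (!is.finite(phi_common)) phi_common <- 0
  phi_tag <- pmax(phi_raw, 0)
  phi_tag[is.na(phi_tag)] <- 0
  phi <- switch(dispersion_mode,
                moderated = shrink * phi_common + (1 - shrink) * phi_tag,
                common = rep(phi_common, nrow(x)),
                tagwise = phi_tag)

  y1 <- round(rowSums(a)); y2 <- round(rowSums(b))
  p <- vapply(seq_len(nrow(x)), function(i)
    nb_exact_p(y1[i], y2[i], n1, n2, phi[i]), numeric(1))
  log2fc <- log2((m_b + 0.5) / (m_a + 0.5))
  q <- bh_adjust(p)
  direction <- ifelse(q < q_max & abs(log2fc) >= lfc_min,
                      ifelse(log2fc > 0, "up", "down"), "ns")
  data.table::data.table(gene = rownames(x),
                         contrast = paste(contrast, collapse = "-"),
                         log2fc = log2fc, p = p, q = q,
                         direction = direction)
}

#' Z-score standardization of expression profiles
#'
#' Per gene: subtract the mean and divide by the standard deviation across
#' all genotype x timepoint replicate means (`level = "mean"`, the heat-map
#' convention) or across all samples (`level = "replicate"`). Zero-variance
#' genes map to all-zero profiles.
#'
#' @param expr genes x samples matrix (counts, RPKM or log scale).
#' @param samples sample sheet (sample, genotype, timepoint).
#' @param level `"mean"` or `"replicate"`.
#' @return standardized matrix; for `level = "mean"` the columns are
#'   `genotype_timepoint` means.
#' @export
zscore <- function(expr, samples, level = c("mean", "replicate")) {
  level <- match.arg(level)
  if (level == "replicate") return(standardize_rows(expr))
  key <- paste(samples$genotype, samples$timepoint, sep = "_")
  groups <- unique(key)
  means <- vapply(groups, function(k)
    rowMeans(expr[, samples$sample[key == k], drop = FALSE]),
    numeric(nrow(expr)))
  dimnames(means) <- list(rownames(expr), groups)
  standardize_rows(means)
}

#' Replicate-mean profiles per genotype x timepoint
#' @inheritParams zscore
#' @return genes x (genotype_timepoint) matrix of replicate means.
#' @export
profile_means <- function(expr, samples) {
  key <- paste(samples$genotype, samples$timepoint, sep = "_")
  groups <- unique(key)
  means <- vapply(groups, function(k)
    rowMeans(expr[, samples$sample[key == k], drop = FALSE]),
    numeric(nrow(expr)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(expr))
  dimnames(means) <- list(rownames(expr), groups)
  means
}
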