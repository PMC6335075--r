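# The T6P-signature layer: metabolite-profile correlation, SnRK1 marker
# panel scoring, and the stringent candidate-gene filter.

#' Correlate gene expression profiles with a metabolite signal
#'
#' Per gene, the Pearson correlation between its per-genotype timepoint
#' replicate means and those of the signal metabolite, concatenated over
#' the requested genotypes. Genes with fewer than 3 aligned points or zero
#' variance are skipped (NA) with a logged count.
#'
#' @param expr genes x samples matrix on the log scale (e.g. log2(RPKM+1)
#'   or log2 counts).
#' @param samples sample sheet (sample, genotype, timepoint).
#' @param metabolites long metabolite table (metabolite, genotype,
#'   timepoint, replicate, abundance).
#' @param metabolite signal metabolite id (default `"T6P"`).
#' @param genotypes genotypes whose timepoints are concatenated (default
#'   conversion line plus the donor parent).
#' @return named vector of signed correlations (use `abs()` for the
#'   absolute mode).
#' @export
correlate_with_signal <- function(expr, samples, metabolites,
                                  metabolite = "T6P",
                                  genotypes = c("CL", "P2")) {
  met <- data.table::as.data.table(metabolites)
  target <- metabolite  # avoid column-name capture in the data.table filter
  met <- met[met$metabolite == target & met$genotype %in% genotypes, ]
  if (nrow(met) == 0) stop("metabolite '", target, "' not found")
  sig <- met[, list(abundance = mean(abundance)),
             by = c("genotype", "timepoint")]
  sig[, key := paste(genotype, timepoint, sep = "_")]

  sub <- samples[samples$genotype %in% genotypes, ]
  gm <- profile_means(expr[, sub$sample, drop = FALSE], sub)
  common <- intersect(colnames(gm), sig$key)
  if (length(common) < 3)
    stop("fewer than 3 aligned genotype x timepoint means")
  gm <- gm[, common, drop = FALSE]
  s <- sig$abundance[match(common, sig$key)]

  sdv <- apply(gm, 1, stats::sd)
  r <- rep(NA_real_, nrow(gm))
  names(r) <- rownames(gm)
  ok <- sdv > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(gm[ok, , drop = FALSE]), s))
  if (any(!ok))
    message("correlate_with_signal: skipped ", sum(!ok),
            " zero-variance gene(s)")
  r
}

#' Score a signed marker panel per genotype x timepoint
#'
#' The panel score is the mean over panel genes of the z-scored expression,
#' with repressed markers negated, so a rising score reads as increasing
#' pathway activity.
#'
#' @param zmat genes x (genotype_timepoint) z-score matrix from [zscore()].
#' @param panel `data.table` with `gene` and `direction`
#'   (induced/repressed) columns, already ortholog-mapped.
#' @return `data.table` (genotype, timepoint, score).
#' @export
marker_panel_score <- function(zmat, panel) {
  panel <- data.table::as.data.table(panel)
  panel <- panel[panel$gene %in% rownames(zmat), ]
  if (nrow(panel) == 0) stop("no panel genes present in the matrix")
  panel <- unique(panel[, c("gene", "direction")])
  sgn <- ifelse(panel$direction == "repressed", -1, 1)
  score <- colMeans(zmat[panel$gene, , drop = FALSE] * sgn)
  parts <- data.table::tstrsplit(names(score), "_")
  data.table::data.table(genotype = parts[[1]], timepoint = parts[[2]],
                         score = as.numeric(score))
}

#' Stringent candidate-gene filter
#'
#' Keeps genes that (1) overlap an introgression segment, (2) are
#' differentially expressed in the conversion line, (3) correlate with the
#' T6P signal at `|r| >= r_min` (or signed `r >= r_min` with
#' `use_abs = FALSE`), and optionally (4) show different trend classes
#' between parent 1 and the conversion line. Deterministic given its
#' inputs; each missing upstream layer raises an error naming it.
#'
#' @param genes gene table (id, chrom, start, end).
#' @param segments introgression segments (chrom, start, end; 0-based
#'   half-open), e.g. from [call_segments()].
#' @param de `data.table` of conversion-line [de_test()] results.
#' @param r named correlation vector from [correlate_with_signal()].
#' @param r_min correlation threshold (default 0.7).
#' @param use_abs use `|r|` (default) or signed r.
#' @param trend_parent1,trend_conv named trend-class vectors (from
#'   [classify_trend()] per gene); both required when
#'   `require_distinct_pattern` is TRUE.
#' @param require_distinct_pattern apply filter (4)?
#' @return `data.table` of passing genes (gene, introgressed, de, r_t6p,
#'   distinct_pattern).
#' @export
candidate_filter <- function(genes, segments, de, r, r_min = 0.7,
                             use_abs = TRUE, trend_parent1 = NULL,
                             trend_conv = NULL,
                             require_distinct_pattern = FALSE) {
  if (is.null(segments)) stop("missing upstream layer: segments")
  if (is.null(de)) stop("missing upstream layer: differential expression")
  if (is.null(r)) stop("missing upstream layer: T6P correlation")
  if (require_distinct_pattern && (is.null(trend_parent1) ||
                                   is.null(trend_conv)))
    stop("missing upstream layer: trend classes")

  intro <- genes_in_segments(genes, data.table::as.data.table(segments))
  de <- data.table::as.data.table(de)
  de_set <- unique(de$gene[de$direction != "ns"])

  out <- data.table::data.table(gene = genes$id)
  out[, introgressed := gene %in% intro]
  out[, de := gene %in% de_set]
  out[, r_t6p := r[gene]]
  rv <- if (use_abs) abs(out$r_t6p) else out$r_t6p
  out[, corr_pass := !is.na(rv) & rv >= r_min]
  if (require_distinct_pattern) {
    out[, distinct_pattern := !is.na(trend_parent1[gene]) &
          !is.na(trend_conv[gene]) & trend_parent1[gene] != trend_conv[gene]]
  } else {
    out[, distinct_pattern := NA]
  }
  pass <- out$introgressed & out$de & out$corr_pass &
    (!require_distinct_pattern | out$distinct_pattern %in% TRUE)
  out[pass, c("gene", "introgressed", "de", "r_t6p", "distinct_pattern")]
}

#' Categorize candidate genes by annotation precedence
#'
#' Each candidate maps to one primary category following the precedence
#' list (first match wins when a gene carries several annotations);
#' unannotated candidates fall into `"unannotated"`.
#'
#' @param candidates character vector of gene ids (or the output of
#'   [candidate_filter()]).
#' @param annotation `data.table` with `gene` and `category` columns.
#' @param precedence ordered category vector.
#' @return `data.table` (category, n), all precedence categories present.
#' @export
categorize_candidates <- function(candidates, annotation,
                                  precedence = c("metabolism", "regulation",
                                                 "transport", "other")) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  ann <- data.table::as.data.table(annotation)
  pick <- vapply(candidates, function(g) {
    cats <- ann$category[ann$gene == g]
    hit <- precedence[precedence %in% cats]
    if (length(hit) > 0) hit[1] else "unannotated"
  }, "")
  levels <- c(precedence, "unannotated")
  counts <- table(factor(pick, levels = levels))
  data.table::data.table(category = levels, n = as.integer(counts))
}
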