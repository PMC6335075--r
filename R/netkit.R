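# Genotype-wise co-expression modules: soft threshold, static-cut module
# detection, eigengenes, kME and permutation-based preservation.

signed_adjacency <- function(expr_std, power) {
  ((1 + stats::cor(t(expr_std))) / 2)^power
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power the signed adjacency is built and the degree
#' distribution binned (equal-width bins on connectivity); the scale-free
#' fit is the R-squared of `log(frequency) ~ log(mean connectivity)` over
#' the non-empty bins. Returns the smallest candidate reaching
#' `rsq_cut`, else the candidate maximizing the fit.
#'
#' @param expr genes x samples matrix (standardized per gene or raw; only
#'   correlations are used).
#' @param candidate_powers increasing vector of powers to try.
#' @param rsq_cut scale-free fit target (default 0.8).
#' @param n_bins number of degree bins (default 10).
#' @return chosen power, with the per-power fit table as attribute `fits`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                                rsq_cut = 0.8, n_bins = 10) {
  if (ncol(expr) < 8)
    warning("fewer than 8 samples; correlation estimates will be unstable")
  cormat <- stats::cor(t(expr))
  fits <- vapply(candidate_powers, function(p) {
    adj <- ((1 + cormat) / 2)^p
    k <- rowSums(adj) - 1
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    if (diff(range(k)) < 1e-12) return(NA_real_)
    bin <- cut(k, breaks, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    usable <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(usable) < 3)
      stop("fewer than 3 usable degree bins; cannot assess scale-free fit")
    fit <- stats::lm(log(freq[usable]) ~ log(kmean[usable]))
    summary(fit)$r.squared
  }, numeric(1))
  ok <- which(!is.na(fits) & fits >= rsq_cut)
  power <- if (length(ok) > 0) candidate_powers[min(ok)]
           else candidate_powers[which.max(fits)]
  attr(power, "fits") <- data.frame(power = candidate_powers, rsq = fits)
  power
}

#' Detect co-expression modules by static tree cut
#'
#' Signed adjacency `((1 + cor)/2)^power`, dissimilarity `1 - adjacency`,
#' average-linkage hierarchical clustering, static cut at `cut_height`
#' (default a quarter of the maximum merge height). Clusters smaller than
#' `min_module_size` are folded into the unassigned module 0. Module ids
#' are ordered by decreasing size.
#'
#' @param expr genes x samples matrix, standardized per gene.
#' @param power soft-threshold exponent.
#' @param min_module_size minimum module size.
#' @param cut_height static cut height; NULL for 0.25 x max merge height.
#' @return object of class `module_set`: labels (named integer vector, 0 =
#'   unassigned), power, cut_height, dendrogram (hclust).
#' @export
detect_modules <- function(expr, power = 6, min_module_size = 30,
                           cut_height = NULL) {
  if (nrow(expr) < min_module_size) {
    labels <- stats::setNames(integer(nrow(expr)), rownames(expr))
    out <- list(labels = labels, power = power, cut_height = NA_real_,
                dendrogram = NULL)
    class(out) <- "module_set"
    return(out)
  }
  adj <- signed_adjacency(expr, power)
  diss <- 1 - adj
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) cut_height <- 0.25 * max(hc$height)
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  # renumber by decreasing size
  keep <- keep[order(-sizes[keep])]
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  names(labels) <- rownames(expr)
  out <- list(labels = labels, power = power, cut_height = cut_height,
              dendrogram = hc)
  class(out) <- "module_set"
  out
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat("<module_set>", length(tab), "modules over", length(x$labels),
      "genes (", sum(x$labels == 0), "unassigned ); power", x$power,
      "cut", signif(x$cut_height, 3), "\n")
  invisible(x)
}

#' Module eigengenes (first principal component per module)
#'
#' The eigengene is the first right singular vector of the module's
#' gene-standardized submatrix (one value per sample, unit norm);
#' `var_explained` is the first squared singular value over the total. The
#' sign is oriented so that the mean correlation with member genes is
#' non-negative.
#'
#' @param expr genes x samples matrix (standardized internally per gene).
#' @param labels named integer module labels (0 = unassigned, skipped).
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `ME<k>`) and `var_explained` (named vector).
#' @export
module_eigengene <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules to summarise")
  E <- matrix(NA_real_, ncol(expr), length(mods),
              dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    x <- standardize_rows(expr[names(labels)[labels == mods[i]], ,
                               drop = FALSE])
    sv <- svd(x)
    v <- sv$v[, 1]
    if (mean(stats::cor(t(x), v)) < 0) v <- -v
    E[, i] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

#' Module membership (kME)
#'
#' kME(gene, module) is the Pearson correlation between the gene's profile
#' and the module eigengene; zero-variance genes get kME 0 by convention.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes samples x modules eigengene matrix.
#' @return genes x modules kME matrix.
#' @export
module_membership <- function(expr, eigengenes) {
  sdv <- apply(expr, 1, stats::sd)
  k <- matrix(0, nrow(expr), ncol(eigengenes),
              dimnames = list(rownames(expr), colnames(eigengenes)))
  ok <- sdv > 0
  if (any(ok)) k[ok, ] <- stats::cor(t(expr[ok, , drop = FALSE]), eigengenes)
  k
}

#' Permutation-based module preservation
#'
#' Observed statistic: mean intramodular signed adjacency of the module's
#' genes in the test data. Null: the same statistic over random gene sets
#' of equal size drawn from the shared universe; `z_summary` standardizes
#' the observation against this null.
#'
#' @param ref_expr reference expression (defines nothing beyond the shared
#'   gene universe; kept for the module-set provenance).
#' @param test_expr test genes x samples matrix.
#' @param labels named module labels on the shared universe.
#' @param n_permutations number of null draws (>= 1; >= 100 recommended).
#' @param power soft-threshold power for the adjacency.
#' @param seed integer seed for the permutation stream.
#' @return `data.table` (module, observed, null_mean, null_sd, z_summary,
#'   n_permutations).
#' @export
module_preservation <- function(ref_expr, test_expr, labels,
                                n_permutations = 100, power = 6,
                                seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  universe <- intersect(rownames(test_expr), names(labels))
  labels <- labels[universe]
  adj <- signed_adjacency(standardize_rows(
    test_expr[universe, , drop = FALSE]), power)
  diag(adj) <- NA
  mean_intra <- function(ids) {
    idx <- match(ids, universe)
    mean(adj[idx, idx], na.rm = TRUE)
  }
  mods <- sort(unique(labels[labels > 0]))
  withr::with_seed(seed, {
    out <- lapply(mods, function(m) {
      ids <- universe[labels == m]
      if (length(ids) > length(universe))
        stop("module larger than universe")
      obs <- mean_intra(ids)
      null <- vapply(seq_len(n_permutations), function(i)
        mean_intra(sample(universe, length(ids))), numeric(1))
      data.table::data.table(module = m, observed = obs,
                             null_mean = mean(null), null_sd = stats::sd(null),
                             z_summary = (obs - mean(null)) /
                               max(stats::sd(null), 1e-12),
                             n_permutations = n_permutations)
    })
  })
  data.table::rbindlist(out)
}

#' Classify a profile's trend by the sign pattern of successive differences
#'
#' Differences within `eps` of zero are flat. Patterns: all flat =>
#' `"flat"`; non-flat steps all positive => `"up"`, all negative =>
#' `"down"`; positive then negative => `"up_down"`; negative then positive
#' => `"down_up"`; anything longer => `"complex"`.
#'
#' @param values numeric profile over ordered timepoints.
#' @param eps flat-band tolerance on the profile's scale.
#' @return character scalar trend class.
#' @export
classify_trend <- function(values, eps = 0.1) {
  d <- diff(unname(as.numeric(values)))
  s <- sign(d) * (abs(d) > eps)
  s <- s[s != 0]
  if (length(s) == 0) return("flat")
  runs <- rle(s)$values
  if (identical(runs, 1)) return("up")
  if (identical(runs, -1)) return("down")
  if (identical(runs, c(1, -1))) return("up_down")
  if (identical(runs, c(-1, 1))) return("down_up")
  "complex"
}
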