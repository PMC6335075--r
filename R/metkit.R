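# Metabolome-side statistics: normalization, PCA, ANOVA with Tukey compact
# letters, Welch tests, differential-metabolite summaries and Brix-sugar
# correlation.

#' Median normalization of metabolite abundances
#'
#' Each run block (the `batch` column, or the whole table when absent) is
#' divided by its median abundance so the block median becomes 1.
#' Idempotent and invariant to rescaling a block.
#'
#' @param table long metabolite `data.table` with an `abundance` column and
#'   optionally a `batch` column.
#' @return normalized copy of the table.
#' @export
median_normalize <- function(table) {
  out <- data.table::copy(data.table::as.data.table(table))
  if (any(out$abundance < 0)) stop("abundances must be non-negative")
  if (!"batch" %in% names(out)) {
    med <- stats::median(out$abundance)
    if (med == 0) stop("zero median abundance")
    out[, abundance := abundance / med]
  } else {
    med <- out[, list(med = stats::median(abundance)), by = "batch"]
    if (any(med$med == 0)) stop("zero median abundance in a batch")
    out <- merge(out, med, by = "batch", sort = FALSE)
    out[, abundance := abundance / med]
    out[, med := NULL]
  }
  out[]
}

#' PCA summary of a samples x variables table
#'
#' Column-standardized principal components via SVD (`prcomp`); variance
#' fractions sum to 1, scores are reproducible up to sign. Zero-variance
#' variables are dropped with a message; an all-constant matrix errors.
#'
#' @param x numeric matrix, samples in rows.
#' @return list with `scores`, `var_frac`, `loadings`.
#' @export
pca_summary <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  sdv <- apply(x, 2, stats::sd)
  if (all(sdv == 0)) stop("constant matrix: no variance to decompose")
  if (any(sdv == 0)) {
    message("pca_summary: dropping ", sum(sdv == 0),
            " zero-variance variable(s)")
    x <- x[, sdv > 0, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  list(scores = pr$x, var_frac = pr$sdev^2 / sum(pr$sdev^2),
       loadings = pr$rotation)
}

tukey_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  g <- unique(groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  ni <- vapply(g, function(x) sum(groups == x), 0L)
  if (any(ni < 2)) stop("need at least 2 replicates per group")
  mi <- vapply(g, function(x) mean(values[groups == x]), 0)
  df <- length(values) - k
  mse <- sum(vapply(g, function(x)
    sum((values[groups == x] - mi[x])^2), 0)) / df
  pairs <- utils::combn(g, 2)
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  pmat <- matrix(1, k, k, dimnames = list(g, g))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (mse == 0) {
      s <- mi[a] != mi[b]
      pv <- if (s) 0 else 1
    } else {
      se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
      q <- abs(mi[a] - mi[b]) / se
      pv <- stats::ptukey(q, k, df, lower.tail = FALSE)
      s <- pv < alpha
    }
    sig[a, b] <- sig[b, a] <- s
    pmat[a, b] <- pmat[b, a] <- pv
  }
  list(groups = g, means = mi, sig = sig, p = pmat, df = df, mse = mse)
}

# insert-and-absorb compact letter display: start with one letter shared by
# all groups; for every significant pair sharing a letter, split that
# letter into two copies lacking one member each; absorb redundant columns
letters_insert_absorb <- function(groups, sig) {
  cols <- list(groups)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in groups) for (b in groups) {
      if (a < b && sig[a, b]) {
        for (ci in seq_along(cols)) {
          if (a %in% cols[[ci]] && b %in% cols[[ci]]) {
            c1 <- setdiff(cols[[ci]], a)
            c2 <- setdiff(cols[[ci]], b)
            cols[[ci]] <- c1
            cols[[length(cols) + 1L]] <- c2
            changed <- TRUE
          }
        }
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(cols[[i]] %in% cols[[j]]) &&
          (length(cols[[i]]) < length(cols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- cols[keep]
  }
  cols <- cols[vapply(cols, length, 0L) > 0]
  cols
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Tukey's honestly-significant-difference test on all group pairs using
#' the studentized-range distribution, followed by the insert-and-absorb
#' compact letter display. Two groups share a letter iff their comparison
#' is non-significant at `alpha`. Letters are assigned in decreasing
#' group-mean order.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param alpha significance level (default 0.05).
#' @return `data.table` (group, mean, letters), plus the pairwise
#'   significance matrix as attribute `sig` and the ANOVA p as attribute
#'   `anova_p`.
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  tk <- tukey_pairwise(values, groups, alpha)
  ord <- names(sort(tk$means, decreasing = TRUE))
  cols <- letters_insert_absorb(ord, tk$sig)
  # order letter columns by the best-ranked member so 'a' goes to the top
  first <- vapply(cols, function(cc) min(match(cc, ord)), 0L)
  cols <- cols[order(first)]
  lab <- vapply(ord, function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, TRUE))],
          collapse = "")
  }, "")
  aov_p <- tryCatch({
    fit <- stats::aov(values ~ factor(groups))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, error = function(e) NA_real_)
  out <- data.table::data.table(group = ord, mean = tk$means[ord],
                                letters = lab)
  data.table::setattr(out, "sig", tk$sig)
  data.table::setattr(out, "anova_p", aov_p)
  out
}

#' Welch's unequal-variance t test
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#'   Zero variance in both samples with equal means gives t = 0, p = 1.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Count significant metabolites per category per genotype
#'
#' Per genotype and metabolite, a one-way ANOVA of abundance over the
#' chosen factor (time by default); metabolites with p < alpha are counted
#' within their category. All category x genotype cells are reported,
#' including zeros.
#'
#' @param table long metabolite table (metabolite, category, genotype,
#'   timepoint, replicate, abundance).
#' @param factor `"timepoint"` (change over time, the default) or
#'   `"genotype"`.
#' @param alpha significance level.
#' @return `data.table` (genotype, category, n_sig, n_total) — for
#'   `factor = "genotype"` the genotype column is `"all"`.
#' @export
diff_metabolite_summary <- function(table, factor = c("timepoint",
                                                      "genotype"),
                                    alpha = 0.05) {
  factor <- match.arg(factor)
  tab <- data.table::as.data.table(table)
  anova_p <- function(values, fac) {
    if (length(unique(fac)) < 2) return(NA_real_)
    stats::anova(stats::lm(values ~ base::factor(fac)))[["Pr(>F)"]][1]
  }
  if (factor == "timepoint") {
    res <- tab[, list(p = anova_p(abundance, timepoint)),
               by = c("genotype", "metabolite", "category")]
  } else {
    res <- tab[, list(p = anova_p(abundance, genotype), genotype = "all"),
               by = c("metabolite", "category")]
  }
  grid <- data.table::CJ(genotype = unique(res$genotype),
                         category = unique(tab$category), unique = TRUE)
  out <- res[, list(n_sig = sum(p < alpha, na.rm = TRUE), n_total = .N),
             by = c("genotype", "category")]
  out <- merge(grid, out, by = c("genotype", "category"), all.x = TRUE)
  out[is.na(n_sig), n_sig := 0L]
  out[is.na(n_total), n_total := 0L]
  out[]
}

#' Brix-total sugar correlation per genotype
#'
#' Pearson correlation between Brix and total sugar (sucrose + glucose +
#' fructose) across matched genotype x timepoint means; fewer than 3
#' matched points yields NA for that genotype.
#'
#' @param brix `data.table` (genotype, timepoint, replicate, brix).
#' @param metabolites long metabolite table containing sucrose, glucose
#'   and fructose rows.
#' @return named vector of correlations per genotype.
#' @export
brix_sugar_correlation <- function(brix, metabolites) {
  met <- data.table::as.data.table(metabolites)
  sug <- met[met$metabolite %in% c("sucrose", "glucose", "fructose"), ]
  tot <- sug[, list(total = sum(abundance)),
             by = c("genotype", "timepoint", "replicate")]
  tot <- tot[, list(total = mean(total)), by = c("genotype", "timepoint")]
  bx <- data.table::as.data.table(brix)[, list(brix = mean(brix)),
                                        by = c("genotype", "timepoint")]
  j <- merge(tot, bx, by = c("genotype", "timepoint"))
  vapply(stats::setNames(unique(j$genotype), unique(j$genotype)),
         function(g) {
    d <- j[j$genotype == g, ]
    if (nrow(d) < 3) return(NA_real_)
    stats::cor(d$total, d$brix)
  }, numeric(1))
}
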