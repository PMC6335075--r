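# Gene-set machinery: hypergeometric over/under-enrichment, BH adjustment,
# ortholog mapping and module x gene-set directional matrices.

#' Hypergeometric tail probability, computed in log space
#'
#' For X ~ Hypergeometric(N, K, n) (universe N, set K, query n), the upper
#' tail is P(X >= k) and the lower tail P(X <= k). Both tails include
#' P(X = k) (standard closed tails). Terms are accumulated in log space
#' from `lchoose`, so extreme p-values keep full relative accuracy.
#'
#' @param k observed overlap, `0 <= k <= min(n, K)`.
#' @param n query size; `n <= N`.
#' @param K set size in the universe; `K <= N`.
#' @param N universe size.
#' @param tail `"upper"` or `"lower"`.
#' @return probability.
#' @export
hypergeom_tail <- function(k, n, K, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("invalid hypergeometric parameters: k=", k, " n=", n, " K=", K,
         " N=", N)
  support <- max(0, n - (N - K)):min(n, K)
  # whole-support tails are exactly 1 by definition
  if (tail == "upper" && k <= support[1]) return(1)
  if (tail == "lower" && k >= support[length(support)]) return(1)
  y <- if (tail == "upper") support[support >= k] else support[support <= k]
  if (length(y) == 0) return(0)
  lterms <- lchoose(K, y) + lchoose(N - K, n - y) - lchoose(N, n)
  min(1, exp(logsumexp(lterms)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1]; NAs propagate.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0) return(q)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
  q
}

#' Read gene sets from a two-column-per-member TSV
#'
#' Expected columns: `set_id`, `species`, `direction`
#' (induced/repressed/none) and `gene`; extra columns pass through.
#'
#' @param path TSV path.
#' @return `data.table` of set memberships.
#' @export
read_genesets <- function(path) {
  gs <- data.table::fread(path, sep = "\t")
  need <- c("set_id", "gene")
  if (!all(need %in% names(gs)))
    stop("gene-set table needs columns: ", paste(need, collapse = ", "))
  if (!"direction" %in% names(gs)) gs[, direction := "none"]
  gs
}

#' Translate gene sets through an ortholog map
#'
#' One-to-many mappings expand, duplicates collapse; unmapped members are
#' dropped with a logged count, and the per-set mapped fraction is attached
#' as attribute `mapped_fraction`. Sets that map to nothing are kept with
#' size 0 and flagged in attribute `empty_sets`.
#'
#' @param sets membership `data.table` (set_id, direction, gene, ...).
#' @param map `data.table` with columns `foreign` and `native`.
#' @return membership table in the native id space.
#' @export
map_orthologs <- function(sets, map) {
  sets <- data.table::as.data.table(sets)
  map <- data.table::as.data.table(map)
  stopifnot(all(c("foreign", "native") %in% names(map)))
  merged <- merge(sets, map, by.x = "gene", by.y = "foreign",
                  allow.cartesian = TRUE)
  out <- unique(merged[, list(set_id, direction, gene = native)])
  n_in <- sets[, list(n = data.table::uniqueN(gene)), by = "set_id"]
  n_out <- out[, list(m = data.table::uniqueN(gene)), by = "set_id"]
  frac <- merge(n_in, n_out, by = "set_id", all.x = TRUE)
  frac[is.na(m), m := 0L]
  dropped <- sum(frac$n) - sum(frac$m)
  if (dropped > 0)
    message("map_orthologs: dropped ", dropped, " unmapped member(s)")
  empty <- frac$set_id[frac$m == 0]
  for (e in empty) {
    message("map_orthologs: set '", e, "' has no mapped members")
    out <- rbind(out, data.table::data.table(
      set_id = e, direction = sets$direction[sets$set_id == e][1],
      gene = NA_character_))
  }
  data.table::setattr(out, "mapped_fraction",
                      stats::setNames(frac$m / pmax(frac$n, 1), frac$set_id))
  data.table::setattr(out, "empty_sets", empty)
  out
}

#' Two-tailed hypergeometric enrichment of query lists against gene sets
#'
#' Queries and sets are intersected with the universe first. Both tails are
#' computed per (query, set); BH is applied within each query across sets,
#' separately per tail. A row is flagged significant when `p <= p_max` and
#' `q <= q_max`.
#'
#' @param query_lists named list of gene-id vectors.
#' @param sets named list of gene-id vectors, or a membership `data.table`
#'   with `set_id`/`gene` columns.
#' @param universe character vector of gene ids (non-empty).
#' @param p_max,q_max significance rule.
#' @return `data.table` (query, set, N, K, n, k, p_over, p_under, q_over,
#'   q_under, sig_over, sig_under).
#' @export
enrich <- function(query_lists, sets, universe, p_max = 0.05, q_max = 0.2) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (data.table::is.data.table(sets) || is.data.frame(sets)) {
    sets <- data.table::as.data.table(sets)
    sets <- split(sets$gene, sets$set_id)
  }
  N <- length(universe)
  rows <- list()
  for (qn in names(query_lists)) {
    qry <- intersect(unique(query_lists[[qn]]), universe)
    for (sn in names(sets)) {
      st <- intersect(unique(stats::na.omit(sets[[sn]])), universe)
      k <- length(intersect(qry, st))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        query = qn, set = sn, N = N, K = length(st), n = length(qry), k = k,
        p_over = hypergeom_tail(k, length(qry), length(st), N, "upper"),
        p_under = hypergeom_tail(k, length(qry), length(st), N, "lower"))
    }
  }
  out <- data.table::rbindlist(rows)
  out[, q_over := bh_adjust(p_over), by = "query"]
  out[, q_under := bh_adjust(p_under), by = "query"]
  out[, sig_over := p_over <= p_max & q_over <= q_max]
  out[, sig_under := p_under <= p_max & q_under <= q_max]
  out[]
}

#' Directional module x gene-set enrichment matrix
#'
#' Each cell is `over` if the module's upper tail is significant, `under`
#' if the lower tail is, and `ns` otherwise (same significance rule as
#' [enrich()]; `over` wins the degenerate case where both flags fire).
#'
#' @param modules a `module_set` (or named integer label vector).
#' @param sets membership `data.table` or named list (ortholog-mapped).
#' @param universe gene universe.
#' @inheritParams enrich
#' @return character matrix modules x sets with entries over/under/ns, the
#'   [enrich()] table as attribute `enrichment`.
#' @export
directional_matrix <- function(modules, sets, universe, p_max = 0.05,
                               q_max = 0.2) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  mods <- sort(unique(labels[labels > 0]))
  queries <- lapply(stats::setNames(mods, paste0("M", mods)),
                    function(m) names(labels)[labels == m])
  er <- enrich(queries, sets, universe, p_max = p_max, q_max = q_max)
  set_names <- unique(er$set)
  mat <- matrix("ns", length(queries), length(set_names),
                dimnames = list(names(queries), set_names))
  for (i in seq_len(nrow(er))) {
    cell <- if (er$sig_over[i]) "over" else if (er$sig_under[i]) "under"
            else "ns"
    mat[er$query[i], er$set[i]] <- cell
  }
  attr(mat, "enrichment") <- er
  mat
}
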