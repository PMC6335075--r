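toy_signal_fixture <- function() {
  # 2 genotypes x 4 timepoints x 2 reps; gene1 tracks the signal exactly,
  # gene2 is its negation, gene3 is constant
  samples <- data.frame(
    sample = paste0("s", 1:16),
    genotype = rep(c("CL", "P2"), each = 8),
    timepoint = rep(rep(paste0("T", 1:4), each = 2), 2),
    replicate = rep(paste0("R", 1:2), 8))
  sig <- c(1, 3, 2, 0.5)
  prof <- rep(rep(sig, each = 2), 2)
  expr <- rbind(gene1 = prof, gene2 = -prof, gene3 = rep(5, 16))
  colnames(expr) <- samples$sample
  met <- data.table::data.table(
    metabolite = "T6P", category = "carbohydrates",
    genotype = rep(c("CL", "P2"), each = 4),
    timepoint = rep(paste0("T", 1:4), 2),
    replicate = "R1", abundance = rep(sig, 2))
  list(expr = expr, samples = samples, met = met)
}

test_that("correlate_with_signal hits the exact and formula cases", {
  fx <- toy_signal_fixture()
  r <- suppressMessages(
    correlate_with_signal(fx$expr, fx$samples, fx$met))
  expect_equal(unname(r["gene1"]), 1)
  expect_equal(unname(r["gene2"]), -1)
  expect_true(is.na(r["gene3"]))

  # formula oracle on a random profile
  withr::with_seed(14, {
    prof <- stats::rnorm(16)
    expr2 <- rbind(g = prof)
    colnames(expr2) <- fx$samples$sample
    r2 <- correlate_with_signal(expr2, fx$samples, fx$met)
    gm <- profile_means(expr2, fx$samples)
    sig_by_key <- stats::setNames(fx$met$abundance,
                                  paste(fx$met$genotype, fx$met$timepoint,
                                        sep = "_"))
    x <- gm[1, ]
    y <- sig_by_key[colnames(gm)]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      ((length(x) - 1) * stats::sd(x) * stats::sd(y))
    expect_equal(unname(r2["g"]), unname(oracle))
  })
  expect_error(correlate_with_signal(fx$expr, fx$samples, fx$met,
                                     metabolite = "nope"), "not found")
})

test_that("marker_panel_score averages signed z-scores", {
  z <- rbind(gA = c(1, 2, 3), gB = c(-1, 0, 1), gC = c(0.5, 0.5, 0.5))
  colnames(z) <- c("CL_T1", "CL_T2", "CL_T3")
  panel1 <- data.table::data.table(gene = "gA", direction = "induced")
  s1 <- marker_panel_score(z, panel1)
  expect_equal(s1$score, c(1, 2, 3))
  # duplicating every panel gene leaves the score unchanged
  panel2 <- data.table::data.table(gene = c("gA", "gB", "gA", "gB"),
                                   direction = "induced")
  panel3 <- data.table::data.table(gene = c("gA", "gB"),
                                   direction = "induced")
  expect_equal(marker_panel_score(z, panel2)$score,
               marker_panel_score(z, panel3)$score)
  # repressed markers are negated
  panel4 <- data.table::data.table(gene = c("gA", "gB"),
                                   direction = c("induced", "repressed"))
  expect_equal(marker_panel_score(z, panel4)$score,
               unname(colMeans(rbind(z["gA", ], -z["gB", ]))))
  expect_error(marker_panel_score(z, panel1[0, ]), "no panel genes")
})

test_that("a planted induced panel rises over time", {
  sim <- small_sim()
  lab <- sim$truth$module_labels
  lat <- sim$truth$latents$CL[2, ]
  genes <- names(lab)[lab == 2]
  dirn <- if (lat[length(lat)] > lat[1]) "induced" else "repressed"
  panel <- data.table::data.table(gene = genes, direction = dirn)
  z <- zscore(log2(sim$counts + 1), sim$samples)
  zc <- z[, grep("^CL_", colnames(z)), drop = FALSE]
  sc <- marker_panel_score(zc, panel)
  sc <- sc[order(sc$timepoint), ]
  # signed score follows the (sign-corrected) module trajectory
  expect_gt(stats::cor(sc$score, if (dirn == "induced") lat else -lat), 0.9)
})

test_that("candidate_filter is the exact intersection of its filters", {
  genes <- data.table::data.table(
    id = paste0("g", 1:5), chrom = "chr1",
    start = c(100, 1100, 2100, 3100, 4100),
    end = c(400, 1400, 2400, 3400, 4400))
  segments <- data.table::data.table(chrom = "chr1", start = 0, end = 2500)
  de <- data.table::data.table(gene = paste0("g", 1:5),
                               direction = c("up", "ns", "down", "up", "up"))
  r <- stats::setNames(c(0.9, 0.95, 0.5, 0.9, 0.99), paste0("g", 1:5))
  out <- candidate_filter(genes, segments, de, r, r_min = 0.7)
  # g1: all pass; g2: not DE; g3: r too low; g4, g5: not introgressed
  expect_identical(out$gene, "g1")

  # independent set algebra
  intro <- paste0("g", 1:3)
  de_set <- paste0("g", c(1, 3, 4, 5))
  corr <- names(r)[abs(r) >= 0.7]
  expect_setequal(out$gene, intersect(intersect(intro, de_set), corr))

  # optional distinct-pattern filter
  tr1 <- stats::setNames(rep("up", 5), paste0("g", 1:5))
  tr2 <- stats::setNames(c("up", rep("up_down", 4)), paste0("g", 1:5))
  out2 <- candidate_filter(genes, segments, de, r, r_min = 0.7,
                           trend_parent1 = tr1, trend_conv = tr2,
                           require_distinct_pattern = TRUE)
  expect_identical(nrow(out2), 0L)   # g1 trends agree -> dropped

  expect_error(candidate_filter(genes, NULL, de, r), "segments")
  expect_error(candidate_filter(genes, segments, NULL, r),
               "differential expression")
  expect_error(candidate_filter(genes, segments, de, NULL), "correlation")
  expect_error(candidate_filter(genes, segments, de, r,
                                require_distinct_pattern = TRUE),
               "trend")
})

test_that("raising r_min never enlarges the candidate set", {
  sim <- small_sim()
  de <- de_test(sim$counts, sim$samples, "CL", c("T1", "T2"))
  r <- suppressMessages(correlate_with_signal(log2(sim$counts + 1),
                                              sim$samples, sim$metabolites))
  prev <- NULL
  for (rm in seq(0.3, 0.9, by = 0.1)) {
    cand <- candidate_filter(sim$genes, sim$truth$segments, de, r,
                             r_min = rm)$gene
    if (!is.null(prev)) expect_true(all(cand %in% prev))
    prev <- cand
  }
})

test_that("categorize_candidates follows the precedence list", {
  ann <- data.table::data.table(
    gene = c("g1", "g2", "g2", "g3", "g4"),
    category = c("regulation", "transport", "metabolism", "other",
                 "regulation"))
  out <- categorize_candidates(c("g1", "g2", "g3", "g5"), ann)
  expect_identical(out$n[out$category == "regulation"], 1L)   # g1
  expect_identical(out$n[out$category == "metabolism"], 1L)   # g2 precedence
  expect_identical(out$n[out$category == "other"], 1L)        # g3
  expect_identical(out$n[out$category == "unannotated"], 1L)  # g5
  # empty candidate list -> all-zero counts
  out0 <- categorize_candidates(character(0), ann)
  expect_identical(sum(out0$n), 0L)
})
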