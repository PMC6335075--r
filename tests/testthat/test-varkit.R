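vcf_lines <- function(body) {
  c("##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    body)
}

test_that("read_vcf maps fields, skips non-SNPs and reports parse errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(character(0)), f)
  expect_identical(nrow(read_vcf(f)), 0L)

  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t1/1:20",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:DP\t1/1:9",   # multiallelic
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t1/1:9",    # indel
    "chr1\t400\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/1:7",
    "chr1\t500\t.\tC\tT\t.\tPASS\t.\tGT:DP\t./.:3")), f)
  expect_message(v <- read_vcf(f), "skipped 2")
  expect_identical(nrow(v), 3L)
  expect_identical(v$gt, c("hom_alt", "het", "missing"))
  expect_identical(v$depth[1], 20L)
  expect_identical(attr(v, "n_skipped"), 2L)

  writeLines(vcf_lines("chr1\toops\t.\tA\tG\t.\t.\t.\tGT\t1/1"), f)
  expect_error(read_vcf(f), "line 3")
  writeLines(c("chr1\t1\t.\tA\tG"), f)
  expect_error(read_vcf(f), "#CHROM")
})

test_that("read_vcf record count matches the truth bookkeeping", {
  sim <- small_sim()
  outdir <- withr::local_tempdir()
  write_fixtures(sim, outdir)
  v <- read_vcf(file.path(outdir, "parent1.vcf"))
  expect_identical(nrow(v), sim$truth$n_snps)
})

test_that("filter_homozygous keeps hom calls above the depth threshold", {
  het <- data.table::data.table(chrom = "c", pos = 1:3, ref = "A", alt = "G",
                                gt = "het", depth = 50L)
  expect_identical(nrow(filter_homozygous(het)), 0L)

  mix <- data.table::data.table(
    chrom = "c", pos = 1:6, ref = "A", alt = "G",
    gt = c("hom_ref", "hom_alt", "het", "missing", "hom_alt", "hom_ref"),
    depth = c(5L, 15L, 50L, 50L, 9L, 12L))
  expect_identical(filter_homozygous(mix, 0)$pos, c(1L, 2L, 5L, 6L))
  # brute-force recount at min_depth = 10
  expect_identical(
    nrow(filter_homozygous(mix, 10)),
    sum(mix$gt %in% c("hom_ref", "hom_alt") & mix$depth >= 10))
  expect_identical(filter_homozygous(mix, 10)$pos, c(2L, 6L))
})

test_that("classify_trio applies the definitional rules", {
  mk <- function(gt, ref = "G", alt = "A") {
    data.table::data.table(chrom = "chr1", pos = 10L, ref = ref, alt = alt,
                           gt = gt, depth = 20L)
  }
  # conv = G/G, p1 = G/G, p2 = A/A -> group1
  expect_identical(
    classify_trio(mk("hom_ref"), mk("hom_ref"), mk("hom_alt"))$group, "group1")
  # conv = A/A, p1 = G/G, p2 = A/A -> group2
  expect_identical(
    classify_trio(mk("hom_alt"), mk("hom_ref"), mk("hom_alt"))$group, "group2")
  # parents agree -> uninformative regardless of conv
  expect_identical(
    classify_trio(mk("hom_alt"), mk("hom_ref"), mk("hom_ref"))$group,
    "uninformative")
  # parent missing from the join -> uninformative
  empty <- mk("hom_ref")[0, ]
  expect_identical(
    classify_trio(mk("hom_ref"), empty, mk("hom_alt"))$group, "uninformative")
  dup <- rbind(mk("hom_ref"), mk("hom_ref"))
  expect_error(classify_trio(dup, mk("hom_ref"), mk("hom_alt")), "duplicate")
})

test_that("classify_trio partitions every joined site into exactly one group", {
  sim <- small_sim()
  cl <- classify_trio(filter_homozygous(sim$snps$conversion),
                      filter_homozygous(sim$snps$parent1),
                      filter_homozygous(sim$snps$parent2))
  expect_true(all(cl$group %in% c("group1", "group2", "uninformative",
                                  "conflicting")))
  expect_identical(nrow(cl), nrow(filter_homozygous(sim$snps$conversion)))
})

test_that("bin_genome applies the min_snps/majority rule", {
  mk_cl <- function(pos, group) {
    data.table::data.table(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                           gt = "hom_alt", depth = 20L, group = group)
  }
  b <- bin_genome(mk_cl(1:10, "group2"), bin_width = 100, min_snps = 5,
                  majority = 0.9)
  expect_identical(b$call, "parent2")
  b <- bin_genome(mk_cl(1:3, "group2"), bin_width = 100, min_snps = 5,
                  majority = 0.9)
  expect_identical(b$call, "unassigned")
  b <- bin_genome(mk_cl(1:10, c(rep("group1", 9), "group2")), bin_width = 100,
                  min_snps = 5, majority = 0.9)
  expect_identical(b$call, "parent1")
  expect_error(bin_genome(mk_cl(1, "group1"), majority = 0.4), "majority")
})

test_that("bin counts conserve the classified SNP totals", {
  sim <- small_sim()
  cl <- classify_trio(filter_homozygous(sim$snps$conversion),
                      filter_homozygous(sim$snps$parent1),
                      filter_homozygous(sim$snps$parent2))
  bins <- bin_genome(cl)
  expect_identical(sum(bins$n_group1) + sum(bins$n_group2),
                   sum(cl$group %in% c("group1", "group2")))
})

test_that("error-free simulation paints exactly the truth bins", {
  cfg <- small_config(genotype_error_rate = 0)
  trio <- simulate_trio(cfg)
  cl <- classify_trio(trio$snps$conversion, trio$snps$parent1,
                      trio$snps$parent2)
  bins <- bin_genome(cl, bin_width = cfg$bin_width,
                     chrom_lens = c(chr1 = cfg$chrom_len))
  segs <- trio$truth$segments
  in_truth <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(segs)))
    in_truth <- in_truth | (bins$chrom == segs$chrom[i] &
                              bins$start >= segs$start[i] &
                              bins$end <= segs$end[i])
  expect_identical(bins$call == "parent2", in_truth)
})

test_that("call_segments merges runs without bridging and attaches genes", {
  bins <- data.table::data.table(
    chrom = "chr1", start = c(0, 100, 200, 300) * 1L,
    end = c(100, 200, 300, 400) * 1L, n_group1 = 0L, n_group2 = 10L,
    call = c("parent2", "parent2", "unassigned", "parent2"))
  seg <- call_segments(bins)
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$n_bins, c(2L, 1L))
  expect_identical(seg$start, c(0, 300))

  bins$call <- "parent1"
  expect_identical(nrow(call_segments(bins)), 0L)
  expect_error(call_segments(bins[c(3, 1, 2), ]), "sorted")
})

test_that("segment gene lists match a brute-force interval-overlap oracle", {
  sim <- small_sim()
  cl <- classify_trio(filter_homozygous(sim$snps$conversion),
                      filter_homozygous(sim$snps$parent1),
                      filter_homozygous(sim$snps$parent2))
  segs <- call_segments(bin_genome(cl), sim$genes)
  expect_gt(nrow(segs), 0)
  for (i in seq_len(nrow(segs))) {
    oracle <- character(0)
    for (j in seq_len(nrow(sim$genes))) {   # O(n * m) on purpose
      g <- sim$genes[j, ]
      if (g$chrom == segs$chrom[i] && g$start <= segs$end[i] &&
          g$end > segs$start[i])
        oracle <- c(oracle, g$id)
    }
    expect_setequal(segs$genes[[i]], oracle)
  }
})

test_that("predict_effect follows the codon rule table", {
  genome <- list(chr1 = paste0("ATG", "TGG", "GCT", "TAA"))
  model <- list(id = "g", chrom = "chr1", strand = "+",
                cds = data.frame(start = 1, end = 12))
  snp <- function(pos, ref, alt) list(chrom = "chr1", pos = pos, ref = ref,
                                      alt = alt)
  # TGG -> TGA (Trp -> stop)
  expect_identical(predict_effect(snp(6, "G", "A"), model, genome)$effect,
                   "HIGH")
  # GCT -> GCC (Ala -> Ala)
  expect_identical(predict_effect(snp(9, "T", "C"), model, genome)$effect,
                   "LOW")
  # GCT -> GTT (Ala -> Val)
  expect_identical(predict_effect(snp(8, "C", "T"), model, genome)$effect,
                   "MODERATE")
  # start loss
  expect_identical(predict_effect(snp(1, "A", "C"), model, genome)$effect,
                   "HIGH")
  # intergenic
  expect_identical(predict_effect(snp(50, "A", "C"), model, genome)$effect,
                   "MODIFIER")
  # broken CDS
  broken <- model
  broken$cds$end <- 11
  expect_warning(out <- predict_effect(snp(5, "G", "A"), broken, genome),
                 "divisible")
  expect_identical(out$effect, "MODIFIER")
})

test_that("splice-site and reverse-strand SNPs are handled", {
  # two exons with an intron; minus strand gene
  genome <- list(chr1 = paste0("TTACAT", "GTAAGT", "AGCCAT"))
  model <- list(id = "g", chrom = "chr1", strand = "-",
                cds = data.frame(start = c(1, 13), end = c(6, 18)))
  # pos 7 and 8 are the first two intron bases -> splice site
  s <- predict_effect(list(chrom = "chr1", pos = 7, ref = "G", alt = "C"),
                      model, genome)
  expect_identical(s$effect, "HIGH")
  expect_identical(s$consequence, "splice_site")
  # mid-intron -> MODIFIER
  expect_identical(
    predict_effect(list(chrom = "chr1", pos = 9, ref = "A", alt = "C"),
                   model, genome)$effect, "MODIFIER")
  # spliced CDS (minus strand) = revcomp(TTACATAGCCAT) = ATGGCTATGTAA
  # pos 2 (T->C) hits codon 4 position 2: TAA -> TGA? verify via oracle
  snp <- list(chrom = "chr1", pos = 2, ref = "T", alt = "C")
  expect_identical(predict_effect(snp, model, genome)$effect,
                   effect_oracle(snp, model, genome))
})

test_that("predict_effect agrees with the translate-both-haplotypes oracle", {
  withr::with_seed(99, {
    for (i in 1:120) {
      toy <- random_gene_model()
      pos <- sample(nchar(toy$genome$chrT), 1)
      ref <- substr(toy$genome$chrT, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      snp <- list(chrom = "chrT", pos = pos, ref = ref, alt = alt)
      got <- suppressWarnings(predict_effect(snp, toy$model, toy$genome))
      want <- effect_oracle(snp, toy$model, toy$genome)
      # start-loss convention: the oracle calls any ATG-start change HIGH
      # only when the first amino acid changes; both routes agree on that
      expect_identical(got$effect, want,
                       info = sprintf("i=%d pos=%d strand=%s", i, pos,
                                      toy$model$strand))
    }
  })
})
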