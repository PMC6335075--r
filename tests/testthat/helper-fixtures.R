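# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small trio-sim config for fast unit tests; overrides replace defaults
small_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 7, n_chrom = 1, chrom_len = 2e6, snp_density = 1e-3,
         n_segments = 2, segment_len_range = c(2e5, 4e5),
         n_genes = 300, n_modules = 3, module_size_range = c(30, 50),
         t6p_set_size = 40, n_candidates = 3, n_metabolites = 16),
    list(...))
  do.call(sim_config, args)
}

small_sim <- function() cached("small_sim", simulate_all(small_config()))

# the spec-default fixture: 5,000 genes, 6 planted modules
default_sim <- function() cached("default_sim", simulate_all(sim_config(seed = 1)))

default_de_cl <- function() cached("default_de_cl", {
  sim <- default_sim()
  de_test(sim$counts, sim$samples, "CL", c("T1", "T2"))
})

# random toy gene model (1-3 CDS exons, both strands) on a random sequence;
# CDS length divisible by 3
random_gene_model <- function(chrom_len = 600) {
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  n_exon <- sample(1:3, 1)
  # pick exon lengths (multiples not required per exon, only in total)
  repeat {
    bounds <- sort(sample(seq(10, chrom_len - 10), 2 * n_exon))
    starts <- bounds[seq(1, 2 * n_exon, by = 2)]
    ends <- bounds[seq(2, 2 * n_exon, by = 2)]
    if (all(ends - starts >= 5) &&
        (n_exon == 1 || all(starts[-1] - ends[-n_exon] >= 7))) break
  }
  len <- sum(ends - starts + 1)
  ends[n_exon] <- ends[n_exon] - (len %% 3)
  model <- list(id = "toy", chrom = "chrT", strand = sample(c("+", "-"), 1),
                cds = data.frame(start = starts, end = ends))
  list(model = model, genome = list(chrT = seq))
}

# brute-force oracle for predict_effect: translate both haplotype CDS
# sequences with Biostrings and classify from the protein comparison
effect_oracle <- function(snp, gene_model, genome) {
  cds <- gene_model$cds[order(gene_model$cds$start), , drop = FALSE]
  pos <- snp$pos
  in_exon <- any(pos >= cds$start & pos <= cds$end)
  if (!in_exon) {
    if (nrow(cds) > 1) {
      for (i in seq_len(nrow(cds) - 1)) {
        intron <- c(cds$end[i] + 1, cds$start[i + 1] - 1)
        if (pos >= intron[1] && pos <= intron[2] &&
            (pos <= intron[1] + 1 || pos >= intron[2] - 1))
          return("HIGH")
      }
    }
    return("MODIFIER")
  }
  splice_seq <- function(chrom_seq) {
    s <- paste(vapply(seq_len(nrow(cds)), function(i)
      substr(chrom_seq, cds$start[i], cds$end[i]), ""), collapse = "")
    if (gene_model$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  ref_seq <- genome[[gene_model$chrom]]
  alt_seq <- ref_seq
  substr(alt_seq, pos, pos) <- snp$alt
  cds_ref <- splice_seq(ref_seq)
  cds_alt <- splice_seq(alt_seq)
  # no.init.codon: use the plain codon table (no initiator special-casing,
  # matching the rule-table semantics)
  aa_ref <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_ref), no.init.codon = TRUE)), "")[[1]]
  aa_alt <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_alt), no.init.codon = TRUE)), "")[[1]]
  diff_at <- which(aa_ref != aa_alt)
  if (length(diff_at) == 0) return("LOW")
  i <- diff_at[1]
  if (aa_ref[i] != "*" && aa_alt[i] == "*") return("HIGH")
  if (aa_ref[i] == "*" && aa_alt[i] != "*") return("HIGH")
  if (i == 1 && substr(cds_ref, 1, 3) == "ATG") return("HIGH")
  "MODERATE"
}

# standardized per-genotype replicate-mean trend classes for candidate_filter
genotype_trends <- function(sim, genotype) {
  pm <- profile_means(log2(sim$counts + 1), sim$samples)
  cols <- grep(paste0("^", genotype, "_"), colnames(pm), value = TRUE)
  std <- t(apply(pm[, cols, drop = FALSE], 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  apply(std, 1, classify_trend)
}
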