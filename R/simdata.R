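#' Simulation configuration for the synthetic trio dataset
#'
#' Builds and validates the configuration object consumed by
#' [simulate_trio()], [simulate_expression()], [simulate_metabolome()] and
#' [simulate_all()]. The defaults state the world the generator emulates: a
#' breeding trio (sweet parent `P1`, grain parent `P2`, conversion line `CL`
#' carrying `P2` segments in a `P1` background), RNA-seq-derived homozygous
#' SNP calls, a 3 genotype x 4 timepoint x 3 replicate expression design with
#' planted co-expression modules, and metabolite time courses including a
#' T6P-like signal with opposite trends between `P1` and `CL`/`P2`.
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   stream from it via [derive_seed()].
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param snp_density informative SNPs per bp between the two parents.
#' @param n_segments number of introgressed segments planted in `CL`.
#' @param segment_len_range length range (bp) of introgressed segments;
#'   lengths are rounded to whole bins so that truth is well defined at the
#'   analysis resolution.
#' @param bin_width genome bin width in bp (breakpoints snap to this grid).
#' @param genotype_error_rate probability that a conversion-line genotype
#'   call is flipped to the other parental allele.
#' @param mean_depth mean per-site sequencing depth (Poisson).
#' @param n_genes number of gene models.
#' @param n_modules number of planted co-expression modules; module 1 always
#'   carries the T6P-regulated gene set.
#' @param module_size_range size range of modules 2..n_modules; module 1 has
#'   exactly `t6p_set_size` members.
#' @param n_timepoints,n_reps expression design (per genotype).
#' @param de_fold planted fold change between timepoints T1 and T2 for the
#'   T6P module and the candidate genes; all planted expression amplitudes
#'   scale with `log2(de_fold)`, so `de_fold = 1` yields a signal-free matrix.
#' @param nb_dispersion negative-binomial dispersion of count noise
#'   (0 = Poisson).
#' @param base_log2_range per-gene baseline expression range on the log2
#'   count scale.
#' @param module_amp amplitude (log2 units, at `de_fold = 4`) of the shared
#'   module trajectories.
#' @param t6p_set_size size of the planted T6P/SnRK1-regulated gene set.
#' @param frac_t6p_in_introgression fraction of the T6P set placed inside
#'   truth introgression segments.
#' @param n_candidates number of planted candidate genes (introgressed,
#'   DE in `CL`, profile proportional to the T6P signal, trend discordant
#'   with `P1`).
#' @param n_metabolites total number of metabolites (including T6P, sucrose,
#'   glucose, fructose).
#' @param met_noise_sd replicate noise sd (log scale) of metabolite
#'   abundances.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 1e7,
                       snp_density = 1e-3,
                       n_segments = 5L,
                       segment_len_range = c(2e5, 8e5),
                       bin_width = 1e5,
                       genotype_error_rate = 0.02,
                       mean_depth = 20,
                       n_genes = 5000L,
                       n_modules = 6L,
                       module_size_range = c(100L, 300L),
                       n_timepoints = 4L,
                       n_reps = 3L,
                       de_fold = 4,
                       nb_dispersion = 0.05,
                       base_log2_range = c(5, 9),
                       module_amp = 1.5,
                       t6p_set_size = 200L,
                       frac_t6p_in_introgression = 0.05,
                       n_candidates = 10L,
                       n_metabolites = 120L,
                       met_noise_sd = 0.1) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = chrom_len, snp_density = snp_density,
              n_segments = as.integer(n_segments),
              segment_len_range = segment_len_range, bin_width = bin_width,
              genotype_error_rate = genotype_error_rate,
              mean_depth = mean_depth, n_genes = as.integer(n_genes),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              n_timepoints = as.integer(n_timepoints),
              n_reps = as.integer(n_reps), de_fold = de_fold,
              nb_dispersion = nb_dispersion,
              base_log2_range = base_log2_range, module_amp = module_amp,
              t6p_set_size = as.integer(t6p_set_size),
              frac_t6p_in_introgression = frac_t6p_in_introgression,
              n_candidates = as.integer(n_candidates),
              n_metabolites = as.integer(n_metabolites),
              met_noise_sd = met_noise_sd)
  assert_count(cfg$n_chrom, "n_chrom")
  assert_count(cfg$n_genes, "n_genes")
  assert_count(cfg$n_timepoints, "n_timepoints")
  assert_count(cfg$n_reps, "n_reps", min = 2)
  assert_count(cfg$n_segments, "n_segments", min = 0)
  assert_count(cfg$n_modules, "n_modules", min = 0)
  assert_count(cfg$n_candidates, "n_candidates", min = 0)
  assert_prob(cfg$genotype_error_rate, "genotype_error_rate")
  assert_prob(cfg$frac_t6p_in_introgression, "frac_t6p_in_introgression")
  if (cfg$chrom_len <= 0 || cfg$bin_width <= 0)
    stop("chrom_len and bin_width must be positive")
  if (cfg$snp_density <= 0 || cfg$snp_density > 1)
    stop("snp_density must be in (0, 1]")
  if (length(cfg$segment_len_range) != 2 ||
      cfg$segment_len_range[1] > cfg$segment_len_range[2])
    stop("segment_len_range must be an increasing pair")
  if (cfg$segment_len_range[1] < cfg$bin_width)
    stop("segment lengths must be at least one bin wide")
  if (cfg$de_fold < 1) stop("de_fold must be >= 1")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$module_size_range[1] < 1 ||
      cfg$module_size_range[1] > cfg$module_size_range[2])
    stop("module_size_range must be a positive increasing pair")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_chrom, "chrom x", format(x$chrom_len, big.mark = ","),
      "bp;", x$n_segments, "segments;", x$n_genes, "genes,", x$n_modules,
      "modules;", x$n_timepoints, "timepoints x", x$n_reps, "reps; seed",
      x$seed, "\n")
  invisible(x)
}

sim_genotypes <- c("P1", "P2", "CL")

# Fixed noiseless metabolite trajectory of the T6P-like signal. P1 dips at
# anthesis (T2) then rises steadily; CL/P2 peak at T2 then fall sharply.
t6p_template <- function(genotype, n_timepoints) {
  stopifnot(n_timepoints >= 3)
  if (genotype == "P1")
    c(0.5, 0.3, seq(0.8, 1.6, length.out = n_timepoints - 2))
  else
    c(0.5, 1.2, seq(0.35, 0.15, length.out = n_timepoints - 2))
}

#' Simulate trio SNP tables with planted introgression segments
#'
#' Parents are homozygous for opposite alleles at every informative site
#' (the homozygous-SNP filter applied to real RNA-seq calls leaves exactly
#' such sites). The conversion line carries the parent-2 allele inside the
#' truth segments and the parent-1 allele elsewhere; its genotype calls are
#' flipped with probability `genotype_error_rate`. Segment breakpoints snap
#' to the bin grid, so an error-free run is recoverable exactly at bin
#' resolution.
#'
#' @param config a [sim_config()] object.
#' @return a list with `snps` (named list of `data.table`s for `parent1`,
#'   `parent2`, `conversion`, each with columns chrom, pos, ref, alt, gt,
#'   depth) and `truth` (segments as 0-based half-open intervals, plus the
#'   config).
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    n_bins <- floor(config$chrom_len / config$bin_width)
    seg_bins_range <- pmax(1L, round(config$segment_len_range / config$bin_width))

    segments <- data.table::data.table(chrom = character(0), start = numeric(0),
                                       end = numeric(0))
    if (config$n_segments > 0) {
      want <- sample(seq(seg_bins_range[1], seg_bins_range[2]),
                     config$n_segments, replace = TRUE)
      # capacity: segments plus a 1-bin gap each so runs never merge
      if (sum(want + 1L) > n_bins * config$n_chrom)
        stop("cannot place ", config$n_segments, " segments of ",
             config$segment_len_range[1], "-", config$segment_len_range[2],
             " bp on ", config$n_chrom, " x ", config$chrom_len,
             " bp; reduce n_segments or segment lengths")
      placed <- vector("list", config$n_segments)
      occupied <- lapply(chroms, function(x) integer(0))
      names(occupied) <- chroms
      for (i in seq_len(config$n_segments)) {
        ok <- FALSE
        for (try in 1:2000) {
          ch <- sample(chroms, 1L)
          start_bin <- sample.int(n_bins - want[i] + 1L, 1L) - 1L
          bins <- seq(start_bin, start_bin + want[i] - 1L)
          # keep a one-bin buffer so neighbouring segments stay distinct
          buffer <- seq(max(0L, start_bin - 1L),
                        min(n_bins - 1L, start_bin + want[i]))
          if (!any(buffer %in% occupied[[ch]])) {
            occupied[[ch]] <- c(occupied[[ch]], bins)
            placed[[i]] <- data.table::data.table(
              chrom = ch,
              start = start_bin * config$bin_width,
              end = (start_bin + want[i]) * config$bin_width)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("segment placement failed after 2000 attempts; ",
               "requested n_segments/lengths do not fit the genome")
      }
      segments <- data.table::rbindlist(placed)
      data.table::setkey(segments, chrom, start)
    }

    bases <- c("A", "C", "G", "T")
    per_chrom <- lapply(chroms, function(ch) {
      n_snp <- round(config$chrom_len * config$snp_density)
      pos <- sort(sample.int(config$chrom_len, n_snp))
      ref <- sample(bases, n_snp, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
      p1_is_ref <- sample(c(TRUE, FALSE), n_snp, replace = TRUE)
      seg_ch <- segments[segments$chrom == ch, ]
      in_seg <- rep(FALSE, n_snp)
      if (nrow(seg_ch) > 0) {
        for (j in seq_len(nrow(seg_ch)))
          in_seg <- in_seg | (pos > seg_ch$start[j] & pos <= seg_ch$end[j])
      }
      data.table::data.table(chrom = ch, pos = pos, ref = ref, alt = alt,
                             p1_is_ref = p1_is_ref, in_seg = in_seg)
    })
    sites <- data.table::rbindlist(per_chrom)

    allele_of <- function(is_ref) ifelse(is_ref, sites$ref, sites$alt)
    p1_allele <- allele_of(sites$p1_is_ref)
    p2_allele <- allele_of(!sites$p1_is_ref)
    conv_is_p2 <- sites$in_seg
    flip <- stats::runif(nrow(sites)) < config$genotype_error_rate
    conv_is_p2 <- xor(conv_is_p2, flip)
    conv_allele <- ifelse(conv_is_p2, p2_allele, p1_allele)

    mk <- function(allele) {
      data.table::data.table(
        chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
        alt = sites$alt,
        gt = ifelse(allele == sites$ref, "hom_ref", "hom_alt"),
        depth = stats::rpois(nrow(sites), config$mean_depth))
    }
    snps <- list(parent1 = mk(p1_allele), parent2 = mk(p2_allele),
                 conversion = mk(conv_allele))

    truth <- list(segments = segments, config = config,
                  n_snps = nrow(sites))
    list(snps = snps, truth = truth)
  })
}

# Draw per-module latent trajectories (unit sd, centered, isotropic in the
# centered subspace). Constraints: pairwise |cor| <= 0.75 within a genotype
# (keeps planted modules separable under the static tree cut); a guaranteed
# T1-T2 step for module 1 (the T6P-regulated set) in CL/P2; and, for P2
# given the already-drawn CL latents, a bound on the CL+P2 concatenated
# correlation with the T6P signature so that no module masquerades as a
# planted candidate in the signature filter.
draw_latents <- function(n_modules, n_tp, need_delta, prev = NULL,
                         t6p_concat = NULL, tries = 20000L) {
  lat <- matrix(0, n_modules, n_tp)
  for (m in seq_len(n_modules)) {
    ok <- FALSE
    for (i in seq_len(tries)) {
      v <- stats::rnorm(n_tp)
      v <- v - mean(v)
      s <- stats::sd(v)
      if (s < 1e-6) next
      v <- v / s
      # module 1 steps by exactly log2(de_fold) after rescaling; bounding
      # the unit step keeps its amplitude >= the other modules' so the
      # module stays detectable
      if (m == 1L && need_delta &&
          (abs(v[2] - v[1]) < 1 || abs(v[2] - v[1]) > 4 / 3)) next
      if (!is.null(prev) &&
          abs(stats::cor(c(prev[m, ], v), t6p_concat)) > 0.45) next
      if (m > 1L &&
          any(abs(stats::cor(v, t(lat[seq_len(m - 1L), , drop = FALSE]))) > 0.75))
        next
      lat[m, ] <- v
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  lat
}

#' Simulate the trio expression matrix with planted modules and candidates
#'
#' Module co-regulation is implemented by shared latent trajectories per
#' module per genotype (pairwise near-orthogonal so planted modules are
#' identifiable). Module 1 is the T6P/SnRK1-regulated set: a configured
#' fraction of its members lies inside the truth introgression segments and
#' its conversion-line trajectory steps by exactly `log2(de_fold)` between
#' T1 and T2. Candidate genes (outside all modules, inside segments) follow
#' the T6P metabolite signature in `CL`/`P2` but a monotone trend in `P1`.
#' Counts are negative binomial around the gene/timepoint means.
#'
#' @param config a [sim_config()] object.
#' @param truth the `truth` element returned by [simulate_trio()].
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample sheet: sample, genotype, timepoint, replicate), `genes` (gene
#'   models: id, chrom, start, end, strand; 1-based inclusive) and the
#'   augmented `truth` (module_labels, de_genes, t6p_set, candidates,
#'   repressed_set, t6p_profile, latents).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 2L), {
    n_tp <- config$n_timepoints
    lfc <- log2(config$de_fold)
    amp <- config$module_amp * lfc / 2  # de_fold = 4 -> amp = module_amp

    # gene models: evenly spaced, length 3 kb, alternating strand
    chroms <- paste0("chr", seq_len(config$n_chrom))
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
    gene_len <- 3000L
    genes <- data.table::rbindlist(lapply(seq_along(chroms), function(i) {
      n <- per_chrom[i]
      if (n == 0) return(NULL)
      spacing <- floor(config$chrom_len / (n + 1))
      if (spacing <= gene_len)
        stop("too many genes for chrom_len; genes would overlap")
      start <- spacing * seq_len(n)
      data.table::data.table(chrom = chroms[i], start = start,
                             end = start + gene_len - 1L,
                             strand = rep_len(c("+", "-"), n))
    }))
    genes[, id := sprintf("gene%05d", seq_len(nrow(genes)))]
    data.table::setcolorder(genes, c("id", "chrom", "start", "end", "strand"))

    introgressed <- genes_in_segments(genes, truth$segments)

    # module membership ---------------------------------------------------
    sizes <- integer(0)
    if (config$n_modules > 0) {
      sizes <- c(config$t6p_set_size,
                 if (config$n_modules > 1)
                   sample(seq(config$module_size_range[1],
                              config$module_size_range[2]),
                          config$n_modules - 1L, replace = TRUE))
    }
    if (sum(sizes) + config$n_candidates > config$n_genes)
      stop("module sizes plus candidates exceed n_genes")

    candidates <- character(0)
    if (config$n_candidates > 0) {
      if (length(introgressed) < config$n_candidates)
        stop("not enough genes inside introgression segments to plant ",
             config$n_candidates, " candidates")
      candidates <- sample(introgressed, config$n_candidates)
    }

    labels <- stats::setNames(integer(nrow(genes)), genes$id)
    if (config$n_modules > 0) {
      k_in <- round(config$frac_t6p_in_introgression * sizes[1])
      avail_in <- setdiff(introgressed, candidates)
      if (k_in > length(avail_in)) {
        message("only ", length(avail_in), " introgressed genes available; ",
                "placing ", length(avail_in), " of ", k_in,
                " T6P-set genes inside segments")
        k_in <- length(avail_in)
      }
      m1_in <- if (k_in > 0) sample(avail_in, k_in) else character(0)
      avail_out <- setdiff(genes$id, c(introgressed, candidates))
      m1_out <- sample(avail_out, sizes[1] - k_in)
      labels[c(m1_in, m1_out)] <- 1L
      pool <- setdiff(genes$id, c(candidates, m1_in, m1_out))
      for (m in seq_len(config$n_modules)[-1]) {
        mem <- sample(pool, sizes[m])
        labels[mem] <- m
        pool <- setdiff(pool, mem)
      }
    }

    # latent trajectories per genotype ------------------------------------
    t6p_concat <- {
      v <- t6p_template("CL", n_tp)
      rep((v - mean(v)) / stats::sd(v), 2)
    }
    latents <- list()
    if (config$n_modules > 0) {
      for (g in c("P1", "CL", "P2")) {  # CL before P2: the joint constraint
        lat <- NULL
        for (restart in 1:50) {
          lat <- draw_latents(config$n_modules, n_tp,
                              need_delta = lfc > 0 && g != "P1",
                              prev = if (g == "P2") latents[["CL"]] else NULL,
                              t6p_concat = if (g == "P2") t6p_concat else NULL)
          if (!is.null(lat)) break
        }
        if (is.null(lat))
          stop("could not draw ", config$n_modules,
               " sufficiently distinct module trajectories for ", n_tp,
               " timepoints; increase n_timepoints or reduce n_modules")
        latents[[g]] <- lat
      }
    }

    # per-module amplitude; module 1 in CL/P2 gets an exact T1-T2 step
    amp_mat <- matrix(amp, max(config$n_modules, 1L), 3,
                      dimnames = list(NULL, sim_genotypes))
    if (config$n_modules > 0 && lfc > 0) {
      for (g in c("P2", "CL"))
        amp_mat[1, g] <- lfc / abs(latents[[g]][1, 2] - latents[[g]][1, 1])
    }

    # candidate signature: scaled centered T6P metabolite template
    cand_tmpl <- list()
    for (g in sim_genotypes) {
      if (g == "P1") {
        # steep monotone rise: the trend class must stay "up" under
        # replicate noise so the discordance with CL/P2 is unambiguous
        cand_tmpl[[g]] <- seq(-1.2, 1.2, length.out = n_tp) * lfc / 2
      } else {
        v <- t6p_template(g, n_tp)
        v <- v - mean(v)
        step <- abs(v[2] - v[1])
        cand_tmpl[[g]] <- if (lfc > 0) v * lfc / step else v * 0
      }
    }

    # expected log2 expression and counts ----------------------------------
    samples <- data.table::CJ(genotype = factor(sim_genotypes, sim_genotypes),
                              timepoint = paste0("T", seq_len(n_tp)),
                              replicate = paste0("R", seq_len(config$n_reps)),
                              sorted = FALSE)
    samples[, genotype := as.character(genotype)]
    samples[, sample := paste(genotype, timepoint, replicate, sep = "_")]
    data.table::setcolorder(samples, c("sample", "genotype", "timepoint",
                                       "replicate"))

    base <- stats::runif(nrow(genes), config$base_log2_range[1],
                         config$base_log2_range[2])
    # candidates are well-expressed genes: their trend classes and signal
    # correlation must be measurable above the count noise
    hi <- mean(config$base_log2_range)
    is_cand_gene <- genes$id %in% candidates
    base[is_cand_gene] <- stats::runif(sum(is_cand_gene), hi,
                                       config$base_log2_range[2])
    loading <- stats::runif(nrow(genes), 0.8, 1.2)
    loading[labels == 1L] <- 1
    loading[is_cand_gene] <- 1

    log2mu <- matrix(base, nrow(genes), nrow(samples))
    tp_idx <- as.integer(sub("T", "", samples$timepoint))
    for (j in seq_len(nrow(samples))) {
      g <- samples$genotype[j]
      t <- tp_idx[j]
      shift <- numeric(nrow(genes))
      if (config$n_modules > 0) {
        in_mod <- labels > 0
        shift[in_mod] <- loading[in_mod] * amp_mat[labels[in_mod], g] *
          latents[[g]][cbind(labels[in_mod], t)]
      }
      shift[is_cand_gene] <- cand_tmpl[[g]][t]
      log2mu[, j] <- log2mu[, j] + shift
    }

    mu <- 2^log2mu
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             nrow(genes), nrow(samples))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow(genes), nrow(samples))
    }
    dimnames(counts) <- list(genes$id, samples$sample)

    # planted DE genes: module members whose latent steps >= log2(de_fold)
    de_genes <- lapply(stats::setNames(sim_genotypes, sim_genotypes),
                       function(g) {
      out <- character(0)
      if (config$n_modules > 0 && lfc > 0) {
        step <- abs(latents[[g]][, 2] - latents[[g]][, 1]) *
          amp_mat[, g]
        de_mod <- which(step >= lfc - 1e-9)
        out <- names(labels)[labels %in% de_mod]
      }
      if (g != "P1" && lfc > 0) out <- union(out, candidates)
      out
    })

    t6p_set <- if (config$n_modules > 0) names(labels)[labels == 1L]
               else character(0)
    repressed_pool <- setdiff(genes$id, c(t6p_set, candidates))
    repressed_set <- sample(repressed_pool,
                            min(config$t6p_set_size, length(repressed_pool)))
    t6p_profile <- lapply(stats::setNames(sim_genotypes, sim_genotypes),
                          t6p_template, n_timepoints = n_tp)

    truth$module_labels <- labels
    truth$de_genes <- de_genes
    truth$t6p_set <- t6p_set
    truth$repressed_set <- repressed_set
    truth$candidates <- candidates
    truth$introgressed_genes <- introgressed
    truth$t6p_profile <- t6p_profile
    truth$latents <- latents

    list(counts = counts, samples = samples, genes = genes, truth = truth)
  })
}

#' Simulate metabolite time courses including the T6P signature
#'
#' The T6P-like metabolite follows fixed noiseless templates: a dip at T2
#' followed by a strictly increasing trajectory in genotype `P1`, and a T2
#' peak followed by a sharp decline in `P2`/`CL` (opposite trends). Sucrose
#' rises steadily in `P1` but peaks and falls in `P2`/`CL`; glucose and
#' fructose fall in all genotypes. The remaining metabolites are flat or
#' monotone per genotype with multiplicative log-normal replicate noise.
#'
#' @param config a [sim_config()] object.
#' @param truth optional truth list (unused; templates are fixed constants
#'   so expression and metabolome stay consistent by construction).
#' @return list with `metabolites` (long table: metabolite, category,
#'   genotype, timepoint, replicate, abundance), `brix` (genotype,
#'   timepoint, replicate, brix) and `changing` (truth: metabolite x
#'   genotype planted changes).
#' @export
simulate_metabolome <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_timepoints < 3) stop("need at least 3 timepoints")
  withr::with_seed(derive_seed(config$seed, 3L), {
    n_tp <- config$n_timepoints
    tps <- paste0("T", seq_len(n_tp))
    cats <- c("amino acids", "carbohydrates", "cofactors", "lipids",
              "nucleotides", "peptides", "secondary metabolites", "hormones")
    up <- seq(0.6, 1.4, length.out = n_tp)
    down <- rev(up)
    flat <- rep(1, n_tp)

    named <- list(
      T6P = lapply(stats::setNames(sim_genotypes, sim_genotypes),
                   t6p_template, n_timepoints = n_tp),
      sucrose = list(P1 = seq(1, 2.2, length.out = n_tp),
                     P2 = c(1, 1.6, seq(1.1, 0.8, length.out = n_tp - 2)),
                     CL = c(1, 1.6, seq(1.2, 0.9, length.out = n_tp - 2))),
      glucose = list(P1 = down, P2 = down, CL = down),
      fructose = list(P1 = down, P2 = down, CL = down))
    named_cat <- c(T6P = "carbohydrates", sucrose = "carbohydrates",
                   glucose = "carbohydrates", fructose = "carbohydrates")

    n_extra <- max(config$n_metabolites - length(named), 0L)
    extra_ids <- sprintf("met%03d", seq_len(n_extra))
    extra_cat <- rep_len(cats, n_extra)

    rows <- list()
    changing <- list()
    emit <- function(id, cat, tmpl_by_geno) {
      for (g in sim_genotypes) {
        tmpl <- tmpl_by_geno[[g]]
        for (t in seq_len(n_tp)) {
          noise <- exp(stats::rnorm(config$n_reps, 0, config$met_noise_sd))
          rows[[length(rows) + 1L]] <<- data.table::data.table(
            metabolite = id, category = cat, genotype = g,
            timepoint = tps[t], replicate = paste0("R", seq_len(config$n_reps)),
            abundance = tmpl[t] * noise)
        }
        if (stats::sd(tmpl) > 1e-9)
          changing[[length(changing) + 1L]] <<- data.table::data.table(
            metabolite = id, genotype = g)
      }
    }
    for (id in names(named)) emit(id, named_cat[[id]], named[[id]])
    for (i in seq_len(n_extra)) {
      tmpl_by_geno <- lapply(stats::setNames(sim_genotypes, sim_genotypes),
                             function(g) {
        if (stats::runif(1) < 0.3) (if (stats::runif(1) < 0.5) up else down)
        else flat
      })
      emit(extra_ids[i], extra_cat[i], tmpl_by_geno)
    }
    metabolites <- data.table::rbindlist(rows)
    changing <- data.table::rbindlist(changing)

    sugars <- metabolites[metabolites$metabolite %in%
                            c("sucrose", "glucose", "fructose"), ]
    brix <- sugars[, list(total = sum(abundance)),
                   by = c("genotype", "timepoint", "replicate")]
    brix[, brix := total * 5 * exp(stats::rnorm(.N, 0, 0.03))]
    brix[, total := NULL]

    list(metabolites = metabolites, brix = brix, changing = changing)
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: [simulate_trio()], then [simulate_expression()],
#' then [simulate_metabolome()], bundled with the shared truth.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `trio_sim`: snps, counts, samples, genes,
#'   metabolites, brix, truth.
#' @export
simulate_all <- function(config) {
  trio <- simulate_trio(config)
  expr <- simulate_expression(config, trio$truth)
  met <- simulate_metabolome(config)
  expr$truth$changing_metabolites <- met$changing
  out <- list(snps = trio$snps, counts = expr$counts, samples = expr$samples,
              genes = expr$genes, metabolites = met$metabolites,
              brix = met$brix, truth = expr$truth)
  class(out) <- "trio_sim"
  out
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("<trio_sim>", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      x$truth$n_snps, "SNP sites;", nrow(x$truth$segments),
      "truth segments;", length(x$truth$t6p_set), "T6P-set genes\n")
  invisible(x)
}

#' Write the synthetic dataset as plain-text fixtures
#'
#' Emits one VCF per genotype, GFF3 gene models, TSV count matrix and sample
#' sheet, gene-set table with an ortholog map (sets are expressed in a
#' foreign id space to exercise cross-species mapping), metabolite and Brix
#' tables, a gene annotation table, and a truth JSON. All files round-trip
#' through the package readers.
#'
#' @param sim a `trio_sim` object from [simulate_all()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the character vector of file paths written.
#' @export
write_fixtures <- function(sim, outdir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  cfg <- sim$truth$config
  contigs <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom),
                             paste0("chr", seq_len(cfg$n_chrom)))
  paths <- character(0)
  p <- function(f) file.path(outdir, f)

  for (g in names(sim$snps)) {
    write_vcf(sim$snps[[g]], p(paste0(g, ".vcf")), sample_name = g,
              contigs = contigs)
    paths <- c(paths, p(paste0(g, ".vcf")))
  }
  write_gff3(sim$genes, p("genes.gff3"))

  counts_dt <- data.table::data.table(gene = rownames(sim$counts))
  counts_dt <- cbind(counts_dt, data.table::as.data.table(sim$counts))
  data.table::fwrite(counts_dt, p("counts.tsv"), sep = "\t")
  data.table::fwrite(sim$samples, p("samples.tsv"), sep = "\t")

  foreign <- function(x) paste0("X_", x)
  sets <- data.table::rbindlist(list(
    data.table::data.table(set_id = "t6p_induced", species = "foreign",
                           direction = "induced",
                           gene = foreign(sim$truth$t6p_set)),
    data.table::data.table(set_id = "t6p_repressed", species = "foreign",
                           direction = "repressed",
                           gene = foreign(sim$truth$repressed_set))))
  data.table::fwrite(sets, p("genesets.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(foreign = foreign(sim$genes$id),
                           native = sim$genes$id),
    p("ortholog_map.tsv"), sep = "\t")

  ann_cat <- withr::with_seed(derive_seed(cfg$seed, 4L),
    sample(c("metabolism", "regulation", "transport", "other"),
           nrow(sim$genes), replace = TRUE,
           prob = c(0.4, 0.25, 0.15, 0.2)))
  data.table::fwrite(
    data.table::data.table(gene = sim$genes$id, category = ann_cat),
    p("annotation.tsv"), sep = "\t")

  data.table::fwrite(sim$metabolites, p("metabolites.tsv"), sep = "\t")
  data.table::fwrite(sim$brix, p("brix.tsv"), sep = "\t")

  truth_json <- list(
    n_snps = sim$truth$n_snps,
    segments = sim$truth$segments,
    module_labels = as.list(sim$truth$module_labels),
    de_genes = sim$truth$de_genes,
    t6p_set = sim$truth$t6p_set,
    repressed_set = sim$truth$repressed_set,
    candidates = sim$truth$candidates,
    introgressed_genes = sim$truth$introgressed_genes,
    t6p_profile = sim$truth$t6p_profile,
    seed = cfg$seed)
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, p(c("genes.gff3", "counts.tsv", "samples.tsv",
                        "genesets.tsv", "ortholog_map.tsv", "annotation.tsv",
                        "metabolites.tsv", "brix.tsv", "truth.json")))
  invisible(paths)
}
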