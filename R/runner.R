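# Configuration-driven orchestration of the full pipeline with a hashed
# output manifest.

pipeline_defaults <- function() {
  list(stages = c("simulate", "introgress", "de", "modules", "enrich",
                  "signature", "metabolome"),
       seed = 1L,
       sim = list(),
       min_depth = 5,
       bin_width = 1e5, min_snps = 5, majority = 0.9,
       contrast = c("T1", "T2"),
       power = 6, min_module_size = 30, cut_height = NULL,
       module_genotype = "CL",
       r_min = 0.7, metabolite = "T6P",
       q_max = 0.05, lfc_min = 1)
}

require_file <- function(stage, path) {
  if (!file.exists(path))
    stop("stage '", stage, "' is missing required input file: ", path,
         call. = FALSE)
  path
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order: `simulate` writes the synthetic fixture
#' set; `introgress` calls introgression segments from the trio VCFs;
#' `de` performs the per-genotype time-course differential-expression
#' tests; `modules` detects co-expression modules in the conversion line;
#' `enrich` runs directional gene-set enrichment (ortholog-mapped);
#' `signature` correlates genes with the T6P signal and applies the
#' candidate filter; `metabolome` summarises metabolite statistics. Later
#' stages consume the files earlier stages wrote, so a simulate-only run
#' followed by a full run works without manual steps.
#'
#' @param config a named list, or the path of a JSON file holding one.
#'   Recognised fields: `out_dir` (required), `stages`, `seed`, `sim`
#'   (overrides for [sim_config()]) and stage parameters (`min_depth`,
#'   `bin_width`, `min_snps`, `majority`, `contrast`, `power`,
#'   `min_module_size`, `module_genotype`, `r_min`, `metabolite`).
#' @return the manifest (list with seed, params and per-file md5 hashes),
#'   invisibly; also written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  outputs <- list()
  note <- function(stage, files) {
    for (f in files)
      outputs[[length(outputs) + 1L]] <<- list(
        stage = stage, file = basename(f),
        md5 = unname(tools::md5sum(f)))
    message("[", stage, "] wrote ", length(files), " file(s)")
  }

  if ("simulate" %in% cfg$stages) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                as.list(cfg$sim)))
    sim <- simulate_all(sc)
    note("simulate", write_fixtures(sim, cfg$out_dir))
  }

  if ("introgress" %in% cfg$stages) {
    conv <- read_vcf(require_file("introgress", out("conversion.vcf")))
    p1 <- read_vcf(require_file("introgress", out("parent1.vcf")))
    p2 <- read_vcf(require_file("introgress", out("parent2.vcf")))
    genes <- read_gff3(require_file("introgress", out("genes.gff3")))
    cl <- classify_trio(filter_homozygous(conv, cfg$min_depth),
                        filter_homozygous(p1, cfg$min_depth),
                        filter_homozygous(p2, cfg$min_depth))
    bins <- bin_genome(cl, bin_width = cfg$bin_width,
                       min_snps = cfg$min_snps, majority = cfg$majority)
    segs <- call_segments(bins, genes)
    write_bed(bins, out("bins.bed"))
    write_bed(segs[, c("chrom", "start", "end", "n_bins")],
              out("segments.bed"))
    writeLines(unique(unlist(segs$genes)), out("introgressed_genes.txt"))
    note("introgress", out(c("bins.bed", "segments.bed",
                             "introgressed_genes.txt")))
  }

  counts <- samples <- NULL
  load_expr <- function(stage) {
    counts_dt <- data.table::fread(require_file(stage, out("counts.tsv")))
    m <- as.matrix(counts_dt[, -1])
    rownames(m) <- counts_dt[[1]]
    list(counts = m,
         samples = data.table::fread(require_file(stage, out("samples.tsv"))))
  }

  if ("de" %in% cfg$stages) {
    ex <- load_expr("de")
    files <- character(0)
    for (g in unique(ex$samples$genotype)) {
      de <- de_test(ex$counts, ex$samples, g, cfg$contrast,
                    q_max = cfg$q_max, lfc_min = cfg$lfc_min)
      f <- out(paste0("de_", g, ".tsv"))
      data.table::fwrite(de, f, sep = "\t")
      files <- c(files, f)
    }
    note("de", files)
  }

  if ("modules" %in% cfg$stages) {
    ex <- load_expr("modules")
    g <- cfg$module_genotype
    cols <- ex$samples$sample[ex$samples$genotype == g]
    lx <- standardize_rows(log2(ex$counts[, cols, drop = FALSE] + 1))
    ms <- detect_modules(lx, power = cfg$power,
                         min_module_size = cfg$min_module_size,
                         cut_height = cfg$cut_height)
    data.table::fwrite(data.table::data.table(gene = names(ms$labels),
                                              module = ms$labels),
                       out("modules.tsv"), sep = "\t")
    if (any(ms$labels > 0)) {
      eg <- module_eigengene(lx, ms$labels)
      data.table::fwrite(
        data.table::data.table(sample = rownames(eg$eigengenes),
                               eg$eigengenes),
        out("eigengenes.tsv"), sep = "\t")
      kme <- module_membership(lx, eg$eigengenes)
      data.table::fwrite(data.table::data.table(gene = rownames(kme), kme),
                         out("kme.tsv"), sep = "\t")
      note("modules", out(c("modules.tsv", "eigengenes.tsv", "kme.tsv")))
    } else {
      note("modules", out("modules.tsv"))
    }
  }

  if ("enrich" %in% cfg$stages) {
    sets <- read_genesets(require_file("enrich", out("genesets.tsv")))
    map <- data.table::fread(require_file("enrich", out("ortholog_map.tsv")))
    sets <- map_orthologs(sets, map)
    mods <- data.table::fread(require_file("enrich", out("modules.tsv")))
    labels <- stats::setNames(mods$module, mods$gene)
    universe <- mods$gene
    dm <- directional_matrix(labels, sets, universe)
    er <- attr(dm, "enrichment")
    data.table::fwrite(er, out("enrichment.tsv"), sep = "\t")
    data.table::fwrite(data.table::data.table(module = rownames(dm), dm),
                       out("directional_matrix.tsv"), sep = "\t")
    note("enrich", out(c("enrichment.tsv", "directional_matrix.tsv")))
  }

  if ("signature" %in% cfg$stages) {
    ex <- load_expr("signature")
    met <- data.table::fread(require_file("signature", out("metabolites.tsv")))
    genes <- read_gff3(require_file("signature", out("genes.gff3")))
    segs <- data.table::fread(require_file("signature", out("segments.bed")),
                              header = FALSE)
    segs <- data.table::data.table(chrom = segs$V1, start = segs$V2,
                                   end = segs$V3)
    de_cl <- data.table::fread(require_file("signature", out("de_CL.tsv")))
    lx <- log2(ex$counts + 1)
    r <- correlate_with_signal(lx, ex$samples, met,
                               metabolite = cfg$metabolite)
    pm <- profile_means(lx, ex$samples)
    tp <- function(g) {
      cols <- grep(paste0("^", g, "_"), colnames(pm), value = TRUE)
      apply(standardize_rows(pm[, cols, drop = FALSE]), 1, classify_trend)
    }
    cand <- candidate_filter(genes, segs, de_cl, r, r_min = cfg$r_min,
                             trend_parent1 = tp("P1"), trend_conv = tp("CL"),
                             require_distinct_pattern = TRUE)
    data.table::fwrite(cand, out("candidates.tsv"), sep = "\t")
    note("signature", out("candidates.tsv"))
  }

  if ("metabolome" %in% cfg$stages) {
    met <- data.table::fread(require_file("metabolome", out("metabolites.tsv")))
    summ <- diff_metabolite_summary(met)
    data.table::fwrite(summ, out("metabolome_summary.tsv"), sep = "\t")
    brix <- data.table::fread(require_file("metabolome", out("brix.tsv")))
    r <- brix_sugar_correlation(brix, met)
    data.table::fwrite(data.table::data.table(genotype = names(r),
                                              r = as.numeric(r)),
                       out("brix_correlation.tsv"), sep = "\t")
    note("metabolome", out(c("metabolome_summary.tsv",
                             "brix_correlation.tsv")))
  }

  manifest <- list(seed = cfg$seed,
                   stages = cfg$stages,
                   params = cfg[setdiff(names(cfg), c("stages", "out_dir"))],
                   outputs = outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
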