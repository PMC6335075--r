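# Trio SNP ingestion, parental-origin classification, genome binning,
# introgression segment calling and variant-effect annotation.

gt_levels <- c("hom_ref", "hom_alt", "het", "missing")

#' Read biallelic SNPs from a VCF 4.x file
#'
#' One record per biallelic SNP line. Multiallelic and indel records are
#' skipped and their count reported via `message()` and the `n_skipped`
#' attribute. Genotypes are taken from the GT field of the first sample
#' (`0/0` hom_ref, `1/1` hom_alt, `0/1`/`1/0` het, otherwise missing);
#' depth from DP when present.
#'
#' @param path path to an uncompressed VCF file.
#' @return `data.table` with columns chrom, pos (1-based), ref, alt, gt,
#'   depth; attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  if (!any(grepl("^#CHROM\t", lines)))
    stop("malformed VCF: missing #CHROM header line in ", path)
  body_idx <- which(!hdr)
  n_skipped <- 0L
  rows <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed VCF row at line ", ln, ": expected >= 8 fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1)
      stop("malformed VCF row at line ", ln, ": bad POS '", f[2], "'")
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L ||
        nchar(alt) != 1L || alt == ".") {
      n_skipped <- n_skipped + 1L
      next
    }
    gt <- "missing"; depth <- 0L
    if (length(f) >= 10) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      val <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt)
      if (!is.na(gi) && gi <= length(val)) {
        g <- gsub("|", "/", val[gi], fixed = TRUE)
        gt <- switch(g, "0/0" = "hom_ref", "1/1" = "hom_alt",
                     "0/1" = "het", "1/0" = "het", "missing")
      }
      di <- match("DP", fmt)
      if (!is.na(di) && di <= length(val)) {
        d <- suppressWarnings(as.integer(val[di]))
        if (!is.na(d)) depth <- d
      }
    }
    rows[[i]] <- list(chrom = f[1], pos = pos, ref = ref, alt = alt,
                      gt = gt, depth = depth)
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) == 0L)
    out <- data.table::data.table(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  gt = character(0), depth = integer(0))
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped,
            " multiallelic/indel records in ", basename(path))
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

#' Write a SNP table as a minimal VCF 4.2 file
#'
#' Inverse of [read_vcf()] for the single-sample SNP tables used throughout
#' the package; homozygous-reference records are emitted explicitly
#' (joint-calling style) so trio comparison sites are never silently absent.
#'
#' @param snps SNP `data.table` (chrom, pos, ref, alt, gt, depth).
#' @param path output path.
#' @param sample_name sample column name.
#' @param contigs optional named vector of contig lengths for the header.
#' @export
write_vcf <- function(snps, path, sample_name = "sample", contigs = NULL) {
  gt_code <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
               missing = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
                  snps$chrom, as.integer(snps$pos), snps$ref, snps$alt,
                  gt_code[snps$gt], as.integer(snps$depth))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene models as GFF3 (gene/mRNA/CDS, single-exon CDS)
#' @param genes gene table (id, chrom, start, end, strand; 1-based).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\tcarballoc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$id),
      sprintf("%s\tcarballoc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$id, g$id),
      sprintf("%s\tcarballoc\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$chrom, g$start, g$end, g$strand, g$id, g$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene spans from a GFF3 file
#' @param path GFF3 path.
#' @return `data.table` (id, chrom, start, end, strand), 1-based inclusive.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.table::data.table(id = as.character(gr$ID),
                         chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr),
                         strand = as.character(GenomicRanges::strand(gr)))
}

#' Keep homozygous calls above a depth threshold
#'
#' The trio comparison is only meaningful at sites where each genotype is
#' confidently homozygous, mirroring the homozygous-SNP filter applied to
#' RNA-seq variant calls.
#'
#' @param snps SNP `data.table` from [read_vcf()].
#' @param min_depth minimum depth (records below are dropped).
#' @return filtered `data.table`, input order preserved.
#' @export
filter_homozygous <- function(snps, min_depth = 0) {
  stopifnot(min_depth >= 0)
  snps[snps$gt %in% c("hom_ref", "hom_alt") & snps$depth >= min_depth, ]
}

snp_allele <- function(snps) {
  ifelse(snps$gt == "hom_ref", snps$ref,
         ifelse(snps$gt == "hom_alt", snps$alt, NA_character_))
}

#' Classify conversion-line SNPs by parental origin
#'
#' At sites where the two parents are homozygous for different alleles, the
#' conversion-line allele decides the group: equal to parent 1 => `group1`,
#' equal to parent 2 => `group2`, equal to neither => `conflicting`. Sites
#' where the parents agree, or where either parent has no call, are
#' `uninformative` (an absent RNA-seq call can mean no expression, not
#' reference allele, so it is never imputed).
#'
#' @param conv,parent1,parent2 homozygous-filtered SNP tables.
#' @return `data.table` of conversion-line sites with added columns
#'   `p1_allele`, `p2_allele`, `group`.
#' @export
classify_trio <- function(conv, parent1, parent2) {
  for (nm in c("conv", "parent1", "parent2")) {
    x <- get(nm)
    if (anyDuplicated(x[, c("chrom", "pos")]))
      stop("duplicate positions within genotype '", nm, "'")
  }
  out <- data.table::copy(data.table::as.data.table(conv))
  out[, conv_allele := snp_allele(out)]
  p1 <- data.table::as.data.table(parent1)[, c("chrom", "pos", "gt", "ref", "alt")]
  p1[, p1_allele := snp_allele(p1)]
  p2 <- data.table::as.data.table(parent2)[, c("chrom", "pos", "gt", "ref", "alt")]
  p2[, p2_allele := snp_allele(p2)]
  out <- merge(out, p1[, c("chrom", "pos", "p1_allele")],
               by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  out <- merge(out, p2[, c("chrom", "pos", "p2_allele")],
               by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  out[, group := "uninformative"]
  informative <- !is.na(out$p1_allele) & !is.na(out$p2_allele) &
    out$p1_allele != out$p2_allele & !is.na(out$conv_allele)
  out[informative & conv_allele == p1_allele, group := "group1"]
  out[informative & conv_allele == p2_allele, group := "group2"]
  out[informative & conv_allele != p1_allele & conv_allele != p2_allele,
      group := "conflicting"]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Paint the genome in fixed-width bins by parental origin
#'
#' Each bin counts group-1 and group-2 SNPs. A bin is called `parent2` iff
#' it holds at least `min_snps` informative SNPs of which a fraction of at
#' least `majority` are group 2 (symmetrically for `parent1`); otherwise it
#' is `unassigned`.
#'
#' @param classified output of [classify_trio()].
#' @param bin_width bin width in bp (default 100 kb).
#' @param min_snps minimum informative SNPs per bin.
#' @param majority required majority fraction, in (0.5, 1].
#' @param chrom_lens optional named vector of chromosome lengths; when
#'   given, empty bins are emitted too (call `unassigned`).
#' @return `data.table` (chrom, start, end, n_group1, n_group2, call) with
#'   0-based half-open coordinates.
#' @export
bin_genome <- function(classified, bin_width = 1e5, min_snps = 5,
                       majority = 0.9, chrom_lens = NULL) {
  stopifnot(bin_width > 0, majority > 0.5, majority <= 1)
  cl <- data.table::as.data.table(classified)
  cl <- cl[cl$group %in% c("group1", "group2"), ]
  cl[, bin := floor((pos - 1) / bin_width)]
  counts <- cl[, list(n_group1 = sum(group == "group1"),
                      n_group2 = sum(group == "group2")),
               by = c("chrom", "bin")]
  if (is.null(chrom_lens)) {
    grid <- cl[, list(bin = seq(0L, max(c(bin, 0L)))), by = "chrom"]
  } else {
    grid <- data.table::rbindlist(lapply(names(chrom_lens), function(ch)
      data.table::data.table(chrom = ch,
                             bin = seq(0L, ceiling(chrom_lens[[ch]] / bin_width) - 1L))))
  }
  bins <- merge(grid, counts, by = c("chrom", "bin"), all.x = TRUE)
  bins[is.na(n_group1), n_group1 := 0L]
  bins[is.na(n_group2), n_group2 := 0L]
  bins[, start := bin * bin_width]
  bins[, end := start + bin_width]
  if (!is.null(chrom_lens))
    bins[, end := pmin(end, chrom_lens[chrom])]
  total <- bins$n_group1 + bins$n_group2
  bins[, call := "unassigned"]
  bins[total >= min_snps & bins$n_group2 / pmax(total, 1) >= majority,
       call := "parent2"]
  bins[total >= min_snps & bins$n_group1 / pmax(total, 1) >= majority,
       call := "parent1"]
  bins[, bin := NULL]
  data.table::setorder(bins, chrom, start)
  data.table::setcolorder(bins, c("chrom", "start", "end", "n_group1",
                                  "n_group2", "call"))
  bins[]
}

#' Merge consecutive parent-2 bins into introgression segments
#'
#' Maximal runs of consecutive `parent2` bins are merged; runs are never
#' bridged across `unassigned` or `parent1` bins. When gene models are
#' supplied, overlapping genes (any overlap, half-open interval
#' intersection) are attached to each segment.
#'
#' @param bins output of [bin_genome()], sorted by (chrom, start).
#' @param genes optional gene table (id, chrom, start, end; 1-based).
#' @return `data.table` (chrom, start, end, n_bins, genes) where `genes` is
#'   a list column of gene ids.
#' @export
call_segments <- function(bins, genes = NULL) {
  b <- data.table::as.data.table(bins)
  if (is.unsorted(order(b$chrom, b$start)) &&
      !identical(order(b$chrom, b$start), seq_len(nrow(b))))
    stop("bins must be sorted by (chrom, start)")
  b <- b[b$call == "parent2", ]
  if (nrow(b) == 0L)
    return(data.table::data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0), n_bins = integer(0),
                                  genes = list()))
  # consecutive = same chrom and abutting coordinates
  new_run <- c(TRUE, b$chrom[-1] != b$chrom[-nrow(b)] |
                 b$start[-1] != b$end[-nrow(b)])
  b[, run := cumsum(new_run)]
  seg <- b[, list(chrom = chrom[1], start = min(start), end = max(end),
                  n_bins = .N), by = "run"]
  seg[, run := NULL]
  seg[, genes := list(list(character(0)))]
  if (!is.null(genes) && nrow(seg) > 0) {
    for (i in seq_len(nrow(seg)))
      data.table::set(seg, i, "genes",
                      list(list(genes_in_segments(genes, seg[i, ]))))
  }
  data.table::setorder(seg, chrom, start)
  seg[]
}

#' Write bins or segments as BED (0-based, half-open)
#' @param x a bins or segments table with chrom, start, end columns; any
#'   further atomic columns are appended after the name column.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  extra <- setdiff(names(x), c("chrom", "start", "end", "genes"))
  out <- data.table::data.table(chrom = x$chrom,
                                start = format(x$start, scientific = FALSE,
                                               trim = TRUE),
                                end = format(x$end, scientific = FALSE,
                                             trim = TRUE))
  out[, name := sprintf("region%d", seq_len(nrow(out)))]
  for (cn in extra) out[[cn]] <- x[[cn]]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Predict the coding effect of a SNP on a gene model
#'
#' Rule table: stop gain, stop loss, start loss, or a splice-site hit
#' (within 2 bp of an intron boundary) => `HIGH`; nonsynonymous codon
#' change => `MODERATE`; synonymous => `LOW`; non-coding or intergenic =>
#' `MODIFIER`. Reverse-strand SNPs are complemented before codon lookup.
#' A CDS whose length is not divisible by 3 yields a warning and `MODIFIER`.
#'
#' @param snp one-row SNP table or list (chrom, pos, ref, alt).
#' @param gene_model list with `chrom`, `strand` ("+"/"-"), and `cds`, a
#'   data.frame of 1-based inclusive exon intervals (start, end) sorted by
#'   start.
#' @param genome named character vector (or list) of chromosome sequences.
#' @param codon_table named translation vector, codon -> amino acid
#'   (default `Biostrings::GENETIC_CODE`).
#' @return list with `effect` (HIGH/MODERATE/LOW/MODIFIER) and
#'   `consequence` (human-readable subtype).
#' @export
predict_effect <- function(snp, gene_model, genome,
                           codon_table = Biostrings::GENETIC_CODE) {
  pos <- as.integer(snp$pos)
  chrom <- as.character(snp$chrom)
  res <- function(effect, consequence) list(effect = effect,
                                            consequence = consequence)
  if (chrom != gene_model$chrom)
    return(res("MODIFIER", "intergenic"))
  cds <- gene_model$cds[order(gene_model$cds$start), , drop = FALSE]
  cds_len <- sum(cds$end - cds$start + 1)
  if (cds_len %% 3 != 0) {
    warning("CDS length not divisible by 3 for gene model; returning MODIFIER")
    return(res("MODIFIER", "broken_cds"))
  }
  in_exon <- which(pos >= cds$start & pos <= cds$end)
  if (length(in_exon) == 0L) {
    # splice region: first/last 2 bases of each intron
    if (nrow(cds) > 1) {
      for (i in seq_len(nrow(cds) - 1L)) {
        intron <- c(cds$end[i] + 1L, cds$start[i + 1L] - 1L)
        if (pos >= intron[1] && pos <= intron[2] &&
            (pos <= intron[1] + 1L || pos >= intron[2] - 1L))
          return(res("HIGH", "splice_site"))
      }
    }
    return(res("MODIFIER", "non_coding"))
  }

  seqs <- vapply(seq_len(nrow(cds)), function(i)
    substr(genome[[chrom]], cds$start[i], cds$end[i]), "")
  spliced <- paste(seqs, collapse = "")
  offset <- c(0, cumsum(cds$end - cds$start + 1))[in_exon]
  cds_pos_plus <- offset + (pos - cds$start[in_exon] + 1L)

  ref <- as.character(snp$ref)
  alt <- as.character(snp$alt)
  if (gene_model$strand == "-") {
    spliced <- revcomp(spliced)
    cds_pos <- cds_len - cds_pos_plus + 1L
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  } else {
    cds_pos <- cds_pos_plus
  }
  if (substr(spliced, cds_pos, cds_pos) != ref)
    warning("reference base mismatch at ", chrom, ":", pos)

  codon_idx <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(spliced, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- codon_table[[ref_codon]]
  alt_aa <- codon_table[[alt_codon]]
  if (is.null(ref_aa) || is.null(alt_aa))
    return(res("MODIFIER", "ambiguous_codon"))
  if (ref_aa != "*" && alt_aa == "*") return(res("HIGH", "stop_gained"))
  if (ref_aa == "*" && alt_aa != "*") return(res("HIGH", "stop_lost"))
  if (codon_idx == 0L && ref_codon == "ATG" && alt_codon != "ATG")
    return(res("HIGH", "start_lost"))
  if (ref_aa == alt_aa) return(res("LOW", "synonymous"))
  res("MODERATE", "missense")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}
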