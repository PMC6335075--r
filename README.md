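# carballoc

Integrative trio analysis of stem sugar accumulation: introgression
mapping from RNA-seq SNPs, genotype-wise co-expression modules,
directional gene-set enrichment against trehalose-6-phosphate
(T6P)/SnRK1-regulated sets, and a stringent candidate-gene filter — with a
ground-truth synthetic-data generator so the whole pipeline is testable
without any external download.

## Who this is for

Plant genomicists and systems biologists working with a **conversion-line
design**: a donor parent (`P2`, e.g. a grain sorghum), a recurrent parent
(`P1`, e.g. a sweet sorghum), and a conversion line (`CL`) carrying a few
`P2` segments in a `P1` background. Given per-genotype VCFs, gene models,
a count matrix over a time course, gene-set tables and metabolite tables,
the package answers:

1. **Where are the introgressions?** Homozygous SNPs at sites where the
   parents disagree are classified by parental origin (`group1` = `P1`
   allele, `group2` = `P2` allele), the genome is painted in 100-kb bins
   by majority vote, and consecutive donor bins merge into segments with
   their overlapping genes.
2. **How does the transcriptome move?** RPKM normalization, a
   negative-binomial exact test between timepoints (median-of-ratios size
   factors, moderated method-of-moments dispersions, BH correction), and
   signed weighted co-expression modules with eigengenes (first principal
   component of a module), kME, and permutation-based preservation
   z-scores.
3. **Is the T6P/SnRK1 signature there?** Two-tailed hypergeometric
   enrichment of each module against induced/repressed gene sets
   (ortholog-mapped, explicit universe), reported as an over/under/ns
   directional matrix: `P(X >= k)` and `P(X <= k)` for
   X ~ Hypergeometric(N, K, n).
4. **Which genes to follow up?** Candidates = genes that overlap an
   introgression segment ∩ are DE in the conversion line ∩ correlate with
   the T6P metabolite profile (`|r| >= 0.7` on replicate means) ∩
   (optionally) change with different trend classes in `P1` vs `CL`.

Metabolome-side statistics (median normalization, PCA, one-way ANOVA with
Tukey HSD compact letters, Welch tests, Brix–sugar correlation) are
included in `metkit`-style helpers.

## Worked example

Simulate a small trio world with known truth, then recover it:

```r
library(carballoc)

cfg <- sim_config(seed = 42, n_chrom = 1, chrom_len = 5e6, n_genes = 1500,
                  n_segments = 3, segment_len_range = c(2e5, 5e5),
                  n_modules = 4, module_size_range = c(60, 120),
                  t6p_set_size = 100, n_candidates = 5, n_metabolites = 40)
sim <- simulate_all(cfg)

cl <- classify_trio(filter_homozygous(sim$snps$conversion, 5),
                    filter_homozygous(sim$snps$parent1, 5),
                    filter_homozygous(sim$snps$parent2, 5))
table(cl$group)
#> group1 group2
#>   3887   1113

segs <- call_segments(bin_genome(cl, chrom_lens = c(chr1 = 5e6)), sim$genes)
segs[, c("chrom", "start", "end", "n_bins")]
#>     chrom   start     end n_bins
#> 1:   chr1  400000  600000      2
#> 2:   chr1  900000 1300000      4
#> 3:   chr1 1700000 2200000      5
```

The three called segments are exactly the planted ones
(`sim$truth$segments`), at bin resolution. `group2` SNPs are the
donor-parent alleles the conversion line carries inside them.

```r
de <- de_test(sim$counts, sim$samples, "CL", c("T1", "T2"))
sum(de$direction != "ns")
#> [1] 382

r <- correlate_with_signal(log2(sim$counts + 1), sim$samples,
                           sim$metabolites)        # vs the T6P profile
cand <- candidate_filter(sim$genes, segs, de, r, r_min = 0.7)
cand
#>         gene introgressed     de     r_t6p distinct_pattern
#> 1: gene00297         TRUE   TRUE 0.9986308               NA
#> 2: gene00303         TRUE   TRUE 0.9859054               NA
#> 3: gene00324         TRUE   TRUE 0.9941869               NA
#> 4: gene00510         TRUE   TRUE 0.9944389               NA
#> 5: gene00516         TRUE   TRUE 0.9919668               NA

sort(sim$truth$candidates)
#> [1] "gene00297" "gene00303" "gene00324" "gene00510" "gene00516"
```

The 382 DE genes are the planted module members whose trajectories step by
at least the planted fold between T1 and T2, and the recovered candidate
set equals the planted one: introgressed, differentially expressed, and
near-perfectly correlated (r ≈ 0.99) with the T6P metabolite signal.

The full pipeline, driven by a JSON config, writes every intermediate as
TSV/BED/VCF/GFF3 plus a hashed manifest:

```sh
exec/carballoc run --config pipeline.json
```

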