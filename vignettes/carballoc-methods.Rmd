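---
title: "carballoc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carballoc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sweet sorghum stores large amounts of sucrose in its stem; grain sorghum
does not. A classical way to dissect such a contrast is a breeding trio: a
sweet parent (`P1`), a grain parent (`P2`), and a conversion line (`CL`)
carrying a handful of `P2` chromosomal segments in an otherwise `P1`
background. Phenotypic differences between `CL` and `P1` can then be
attributed to the introgressed segments. carballoc implements the
computational side of that dissection: it locates the introgressions from
RNA-seq SNP calls, characterises the transcriptome dynamics of the three
genotypes with co-expression networks, asks whether the conversion line's
transcriptome bears the signature of trehalose-6-phosphate (T6P)/SnRK1
sugar signalling, and finally filters for candidate genes that are
introgressed, differentially expressed, and correlated with the T6P
metabolite signal.

Because the field data behind this design are not publicly available, the
package ships a first-class synthetic-data generator (`simulate_all()`)
whose outputs exercise every stage with known ground truth. All quantitative
claims the test suite makes are claims about that stated world.

# Introgression mapping

SNPs are called per genotype against a common reference, so the trio
comparison works on three single-sample tables (`read_vcf()`). Only
confidently homozygous calls enter the comparison (`filter_homozygous()`):
at a site where the parents are homozygous for *different* alleles, the
conversion-line allele identifies its parental origin (`classify_trio()`):
`group1` = same allele as `P1`, `group2` = same allele as `P2`. Sites where
the parents agree are uninformative; sites absent from a parent are also
uninformative — in RNA-seq an absent call may simply mean the gene is not
expressed there, so absence is never imputed as the reference allele.

The genome is painted in fixed-width bins (100 kb by default,
`bin_genome()`). A bin is assigned to a parent when it holds at least
`min_snps` informative SNPs (default 5) of which at least a `majority`
fraction (default 0.9) agree. These two thresholds are not printed in the
source study (only the bin width is); the defaults suppress single-SNP
noise and are exposed in the configuration. Consecutive `parent2` bins
merge into segments (`call_segments()`); runs are never bridged across
unassigned bins — conservative, and it avoids inventing a smoothing model.
Internally all intervals are 0-based half-open; VCF and GFF3 coordinates
are converted at the boundary.

`predict_effect()` classifies coding SNPs with a documented rule table
(stop gain/loss, start loss, splice site within 2 bp of an intron boundary
=> HIGH; missense => MODERATE; synonymous => LOW; everything else =>
MODIFIER). The original study's effect predictor is not described in the
available text, so this rule table is a stand-in; its correctness is
checked against an independent translate-both-haplotypes oracle rather
than against the study's counts. The plain codon table is used without
initiator special-casing (a CTG->ATG change is a missense, not a
synonymous initiator swap).

# Expression and differential expression

Normalization is RPKM with the usual `log2(RPKM + 1)` companion transform.
The source study intersected DESeq and edgeR calls; re-implementing both
engines is out of scope, so `de_test()` provides a single documented
negative-binomial exact test between two timepoints of one genotype:

* Library scaling uses **median-of-ratios size factors**. Total-count
  scaling is biased when differential expression is coherent and
  asymmetric (exactly the planted-module situation, and a common real-data
  situation); the median ratio over genes is robust to it.
* Per-gene dispersions are estimated by method of moments and shrunk
  halfway toward a common value. The common value is the mean of the
  *unfloored* per-gene estimates: flooring negatives at zero before
  pooling biases the pool low and makes the exact test anti-conservative
  (this is visible in the type-I calibration test, which the floored
  variant fails).
* The test conditions on the gene's total count: with a common dispersion
  φ, replicate sums are negative binomial, and the double tail sums all
  outcomes at most as probable as the observation.
* Significance: BH-adjusted `q < 0.05` and `|log2FC| >= 1`, both
  config-exposed since the study does not print its cut-offs.

Calibration on the stated null (2,000 genes, μ in 2^5..2^9, φ = 0.05,
n = 3 vs 3) gives empirical type-I of about 0.06 at p < 0.05 and power 1.0
for 4-fold changes at q < 0.05; both are recomputed by
`scripts/acceptance.R`.

# Co-expression modules

`detect_modules()` builds a signed adjacency `((1 + cor) / 2)^power`,
converts it to a dissimilarity, clusters by average linkage, and applies a
**static** tree cut (default height: a quarter of the maximum merge
height). The original WGCNA workflow uses a dynamic tree cut; the static
cut was chosen because it is fully specifiable and testable — the price is
one tunable height, which is exposed. Clusters smaller than
`min_module_size` (default 30) fall back to the unassigned module 0.

Eigengenes are first right singular vectors of the gene-standardized
module submatrix, with `var_explained` the first squared singular value
over the total. The sign convention — orient so that the mean correlation
with member genes is non-negative — is needed for reproducible plots and
kME signs and is not stated in the source study. kME is the plain Pearson
correlation of a gene with an eigengene; zero-variance genes get kME 0.

Module preservation uses a single statistic (mean intramodular adjacency
in the test data) against a permutation null of random equal-size gene
sets, summarised as a z-score. The original method aggregates many
statistics; at desk scale one statistic preserves the qualitative contract
(large z = preserved) and stays cheap enough for seeded permutation
testing.

Eigengene trends are classified by the sign pattern of successive
differences with a flat band of ±0.1 (`classify_trend()`): up, down,
up_down, down_up, flat, or complex. These classes also implement the
"distinct pattern" criterion of the candidate filter.

`pick_soft_threshold()` follows the scale-free criterion: smallest
candidate power whose degree distribution fits a power law with R² ≥ 0.8
over ≥ 10 log-log bins, falling back to the best-fitting power.

# Gene sets and directional enrichment

`hypergeom_tail()` computes closed tails (both include P(X = k); the
study does not state its convention, so the standard one is used) in log
space from `lchoose`, so p-values such as 1e-30 keep full relative
accuracy. It is validated against exhaustive enumeration of all draws for
every universe size up to 12.

`enrich()` forces an explicit universe. This is deliberate: the study's
printed hypergeometric p-values are not reproducible precisely because its
universes are unprinted, so the package refuses to default one silently.
BH runs within each query across sets, separately per tail, matching the
per-module reading of the study's enrichment displays. The directional
matrix marks each module × set cell over/under/ns; cross-species sets
pass through `map_orthologs()` first (one-to-many expands, duplicates
collapse, unmapped members are dropped with a logged count).

# The T6P signature and candidate genes

`correlate_with_signal()` correlates each gene's genotype × timepoint
replicate means with the metabolite signal over the concatenated profiles
of the conversion line and the donor parent — the two genotypes that share
the inverted T6P dynamics. Both signed and absolute thresholds are
supported because the study does not state which it used; the default
filter uses `|r| >= 0.7` on replicate-mean profiles (config-exposed).

`candidate_filter()` is a pure set intersection: introgressed ∩ DE in the
conversion line ∩ T6P-correlated, optionally ∩ trend-discordant between
`P1` and `CL`. It is deterministic given its inputs and is tested against
independent set algebra; raising `r_min` can only shrink the output.
`marker_panel_score()` summarises a signed marker panel (induced genes
count positively, repressed negatively) per genotype × timepoint.

# Metabolome statistics

Median normalization per run block; PCA on column-standardized data via
SVD; one-way ANOVA with Tukey HSD using the studentized-range
distribution; compact letters by the insert-and-absorb algorithm, which
guarantees (and the tests brute-force check) that two groups share a
letter exactly when their comparison is non-significant; Welch's t with
Satterthwaite degrees of freedom, validated against a 10^5-permutation
approximation; per-category counts of time-significant metabolites; and
Brix vs total-sugar correlation. Missing-value imputation (per-metabolite
minimum) is exposed rather than hard-coded because the study does not
state its handling. Whether the differential-metabolite summary counts
changes over time or between genotypes is ambiguous in the source; the
factor is an argument (`factor = "timepoint"` by default).

# The synthetic world

The generator's defaults state the world once:

* **Trio SNPs** — 2 chromosomes × 10 Mb, one informative SNP per kb;
  parents homozygous for opposite alleles (the homozygous filter leaves
  exactly such sites); 5 introgressed segments of 200–800 kb with
  breakpoints snapped to the 100-kb bin grid — breakpoints below marker
  resolution are unidentifiable, so truth is defined at the analysis
  resolution; conversion-line genotypes flipped at 2% (the parents are the
  marker definition and stay error-free; an error in a parent makes the
  site uninformative upstream, it does not mislocate a segment); Poisson
  depth around 20×.
* **Expression** — 5,000 genes × 3 genotypes × 4 timepoints × 3
  replicates; negative-binomial counts with dispersion 0.05 (a ~22%
  biological CV) over baselines of 2^5..2^9. Six planted modules share
  latent trajectories per genotype, drawn isotropically in the centered
  trajectory space with pairwise |cor| ≤ 0.75 — with only four timepoints
  the shape space is three-dimensional, so perfectly orthogonal modules do
  not exist; the bound keeps between-module merges well above the static
  cut. Module 1 is the T6P/SnRK1-regulated set (200 genes, a configurable
  fraction inside true segments); its conversion-line trajectory steps by
  exactly log2(de_fold) between T1 and T2, with the unit step bounded so
  the rescaled amplitude never drops below the other modules'. All planted
  amplitudes scale with log2(de_fold), so `de_fold = 1` yields a
  signal-free matrix.
* **Candidates** — 10 genes outside all modules, inside true segments,
  drawn from the upper half of the expression range (their trend classes
  and correlations must be measurable above count noise); their `CL`/`P2`
  profiles follow the T6P metabolite template, their `P1` profile a steep
  monotone rise. Module trajectories for `CL`/`P2` are jointly constrained
  to concatenated |cor| ≤ 0.45 with the T6P signature so that no module
  masquerades as a candidate.
* **Metabolome** — fixed noiseless templates (T6P dips then rises in `P1`,
  peaks at anthesis then falls in `CL`/`P2`; sucrose keeps rising only in
  `P1`; glucose/fructose fall everywhere) with 10% log-normal replicate
  noise; Brix proportional to total sugar with 3% noise.

What a green test does *not* establish: the generator has no batch
effects, no library-size gradients, no isoform structure, no
heteroskedastic metabolite panels, and its module trajectories are
genotype-coherent by construction — real co-expression is messier in all
these directions. Conclusions about the original study's biology are out
of scope; the tests establish that the implementations honour their
contracts on a world where truth is known.

# Known limitations

* With 5,000 background genes, a single null gene occasionally (roughly
  one seed in five to ten) survives all four candidate filters at once —
  a chance DE call × chance 8-point correlation × introgression overlap.
  The candidate filter is exact set algebra, so this is a property of any
  finite threshold rule, not a defect; the acceptance fixture documents
  exact recovery at its stated seed and the report script prints the
  Jaccard overlap it actually measured.
* The NB exact test is mildly liberal (type-I ≈ 0.06–0.07 at nominal
  0.05, occasionally a shade above 0.07 on unlucky seeds) because
  dispersion-estimation uncertainty is ignored; worth knowing before reuse
  at scale.
* `pick_soft_threshold()` measures scale-free fit on equal-width degree
  bins; on very small gene sets (< ~100) the bin count limits resolution.
* Four timepoints support at most a handful of separable module shapes;
  configurations asking for many modules at few timepoints are rejected
  with a sizing error rather than silently producing confounded truth.
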