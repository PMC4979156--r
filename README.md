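# tenet — transposable element neighborhoods and histone modification changes

`tenet` is an R package for asking a gene-centric question in cancer
epigenomics: **do genes with transposable elements (TEs) in their
neighborhood experience larger chromatin changes — and more expression
change — than TE-free genes when the cellular condition changes?**
It was built for comparisons such as a normal lymphoblastoid versus a
leukemic blood cell line, but every step works on any pair of conditions
with gene annotations, RepeatMasker TE copies, broadPeak histone ChIP-seq
intervals, and a differential-expression table.

## What it computes

For each gene `g`, over its *vicinity* (gene body ± 2 kb flanks, reaching
the promoter), with `N` overlapping TE copies covering `L_TE` of the
`L_g` vicinity bases (clipped, union-merged):

```
density    D_g = N / (L_g − L_TE)        copies per non-TE bp
coverage   C_g = L_TE / L_g              TE-derived fraction, in [0, 1]
```

both overall and per TE class (DNA, LTR, LINE, SINE). Per-gene mean
histone enrichment ε(h) summarizes broadPeak fold-enrichment over the
gene body for each of the ten marks (H3K4me1/2/3, H3K9ac, H3K9me3,
H3K27ac, H3K27me3, H3K36me3, H3K79me2, H4K20me1) and condition. Genes are
then classified by a from-scratch, fully deterministic PAM (k-medoids)
clustering into TE-free / TE-intermediate / TE-rich and into a 12-way
type-specific scheme (`SINE-rich`, ..., `All-TE-rich`, `Mix`), profiled
along chromosomes in 5 % bins, and compared across conditions with paired
Wilcoxon, Kruskal-Wallis, and Pearson chi-square homogeneity tests under
Bonferroni control (`α/n`). A synthetic-genome generator with planted
ground truth backs the whole test suite.

## Worked example

```r
library(tenet)

sim     <- simulate_genome(sim_config(seed = 1))   # planted ground truth
metrics <- te_metrics(sim$genes, sim$tes, chrom_lengths = sim$chrom_lengths)
head(metrics[, c("gene_id", "L_g", "n_all", "lte_all", "density_all", "coverage_all")], 4)
#>   gene_id   L_g n_all lte_all density_all coverage_all
#> 1   G0001  6060     0       0    0.000000        0.000
#> 2   G0002  7349     2     862    0.000308        0.117
#> 3   G0003  5817     0       0    0.000000        0.000
#> 4   G0004 11813    16    6514    0.003019        0.551
```

Gene G0001 has no TE within 2 kb (TE-free); G0004's neighborhood is 55 %
TE-derived. Density and coverage rank genes almost identically
(`density_coverage_correlation(metrics)` gives Spearman ρ = 0.90,
p = 4.5e-72, n = 200), and PAM recovers the planted three-level split:

```r
classes <- classify_genes(metrics)
table(classes$level3)
#>         TE-free TE-intermediate         TE-rich
#>              47             104              49
```

The condition layer: H3K27me3 (a repressive mark) was planted with a
positive shift in the cancer condition for TE-carrying genes, and the
paired test sees it,

```r
enr  <- enrichment_matrix(sim$genes, sim$peaks)
paired_condition_test(enr, "H3K27me3", "normal", "cancer", n_tests = 10)
#>              test statistic        p   n alpha_bonferroni significant
#> 1 wilcoxon-paired       736 6.36e-30 200            0.005        TRUE
```

while the contingency layer shows *which* genes changed: among genes
clearly more H3K27me3-enriched in cancer (|Δε| > 1), TE-free genes
vanish (0 % versus 23.5 % genome-wide) and the chi-square homogeneity
test against the genome column rejects,

```r
diff <- differential_enrichment(enr, "normal", "cancer", tau = 1)
grp  <- enrichment_direction_sets(diff, "H3K27me3", "enriched-in-B", tau = 1)
cont <- build_contingency(classes, list(total_genome = classes$gene_id,
                                        H3K27me3_enriched = grp))
chi2_homogeneity(cont, "H3K27me3_enriched", "total_genome")
#>               test statistic        p   n alpha_bonferroni significant df
#> 1 chi2-homogeneity      40.8 1.25e-05 150             0.05        TRUE 10
```

`run_pipeline()` chains all stages over files on disk and writes one TSV
per stage plus a manifest; `simulate_genome(..., out_dir = ...)` emits a
complete file set (GTF, TE TSV, broadPeaks, DE table, chrom.sizes) to
feed it.

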