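# teprom

Transposable-element content of gene promoters and expression dynamics in
early embryonic development.

## The problem

During pre-implantation development, mammalian embryos rebuild their
transcriptome in waves: maternal transcripts decay, a transient burst marks
the 2-cell stage, and broad zygotic genome activation (ZGA) follows.
Repetitive elements are unevenly placed around promoters — SINEs (mouse B1,
human Alu) cluster near genes while LINEs avoid them, and LTR
retrotransposons of the MERV-L group carry their own promoters — and their
presence correlates with which genes come up at which stage.

`teprom` is an analysis pipeline for quantifying that association. It is
written for computational biologists who want to run the complete chain —
promoter construction, strand/distance-resolved repeat feature extraction,
enrichment/dosage/distance/regression statistics, motif-score ANOVA, and
genome-wide repeat distribution statistics — on their own annotation +
expression data, or to validate the statistical machinery on a fully
synthetic genome with known planted effects.

## The model

The central estimate is a per-copy effect on the log2 stage fold-change.
With `y_g` the log2 fold-change of gene `g` between two stages and
`x_{g,t,o}` the number of copies of repeat type `t` in orientation
`o ∈ {same, opposite}` (relative to the gene) within the 2 kb upstream
promoter window,

```
y_g = α + Σ_{t,o} β_{t,o} · x_{g,t,o} + ε_g
```

fitted by OLS with Welch t-tests and Benjamini–Hochberg FDR for the
surrounding battery: chi-square cluster enrichment (in-cluster vs all other
clusters combined), dosage curves over copy-number categories (0…4, ≥5),
distance-to-TSS curves, rank-bin correlation (groups of genes sorted by
fold-change), hypergeometric gene-set over-representation, PWM log-odds
scanning with one-way ANOVA of maximal scores over fold-change-ranked
groups, lognormal copy-number fits, region enrichment
(promoter > exon > intron > downstream > intergenic by midpoint) and
strand-preference chi-squares against a 50:50 null.

A seeded generator (`sim_config()` / `simulate_bundle()`) emits a complete
input bundle — GTF, RepeatMasker `.out`, BED, expression + design TSVs,
MEME motifs, optional FASTA — with three planted repeat families (SINE-like
both-strand effect with weak distance decay, LTR-like same-strand-only
effect with sharp decay, LINE-like null) and full ground truth, so every
estimator can be checked end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic bundle (`Rscript analysis/01_simulate.R` through
`09_genesets_orthologs.R`; outputs land in `results/`). The core of it in a
session:

```r
library(teprom)

b    <- simulate_bundle(sim_config(seed = 1))
prom <- make_promoters(b$tss, upstream = 2000, downstream = 0, b$contig_lengths)
ft   <- build_feature_table(prom, b$repeats, level = "name")
fc   <- fold_change(b$expr, "mid2C", "late2C", pseudocount = 0)

cnt <- setNames(ft$count.name.B1_Sim.any, ft$gene_id)
dosage_analysis(cnt, fc)
```

```
   category n_genes mean_log2fc         se   p_vs_prev  stars
1:        0     367   0.5822807 0.08184745          NA
2:        1     642   0.8123471 0.06247507 0.025745298      *
3:        2     517   0.9800126 0.06889393 0.071690599
4:        3     284   1.1792925 0.09137627 0.082136581
5:        4     126   1.6555865 0.15261381 0.007977785     **
6:      >=5      64   2.1434815 0.20524308 0.058622160
```

Mean late-2C fold-change climbs monotonically with the number of SINE-like
copies in the promoter — about 0.25 log2 units (≈ 1.2-fold expression) per
copy, matching the planted per-copy effect of 0.3 attenuated by the
distance-decay weight inside the window (effective value 0.250, reported in
`b$truth`). The orientation-split regression on the same table:

```r
X <- as.matrix(ft[, grep("[.](same|opposite)$", names(ft)), with = FALSE])
rownames(X) <- ft$gene_id
multiple_regression(fold_change(b$expr, "early2C", "mid2C", pseudocount = 0), X)
```

recovers the LTR-like family's same-strand-only effect
(`count.name.MT2_Sim.same` = 0.585 ± 0.101, FDR 5×10⁻⁸; opposite strand
0.65 FDR, n.s.) against an effective planted value of 0.567, and the
distance curve (`analysis/05`) shows the effect confined to the first
kilobase (+1.01 log2 units vs no-copy genes, p = 1×10⁻¹¹) and flat beyond
the planted 800 bp decay scale. The LTR-like family's planted placement
bias also shows up genome-wide: `strand_preference()` on promoters reports
a 4.10:1 same:opposite ratio (chi-square p ≈ 10⁻³¹).

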