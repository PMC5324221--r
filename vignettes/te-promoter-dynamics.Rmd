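---
title: "Repeat content of promoters and early embryonic expression dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat content of promoters and early embryonic expression dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

During pre-implantation development the embryonic genome switches on in
waves: maternal transcripts decay, a transient burst of expression marks the
2-cell stage, and broad zygotic genome activation (ZGA) follows. Repetitive
elements — SINEs such as mouse B1, LTR retrotransposons such as the MERV-L
group, and LINEs — are unevenly distributed around gene promoters, and their
presence correlates with which genes come up when.

`teprom` implements the full exploratory pipeline that quantifies this
association: strand-aware promoter windows around expression-selected TSSs;
per-gene feature tables of repeat counts (split by orientation relative to
the gene), coverage and distance-to-TSS; stage fold-changes and gene
clustering; an association battery (cluster enrichment, dosage and distance
curves, rank-bin correlation, orientation-split multiple regression,
per-sample expression-count correlation, ortholog deltas, gene-set
over-representation); PWM scanning with group ANOVA; and genome-wide repeat
distribution statistics.

The central quantitative model is linear on the log2 scale: writing
$y_g$ for the log2 fold-change of gene $g$ between two stages and
$x_{g,t,o}$ for the number of copies of repeat type $t$ in orientation
$o \in \{\text{same}, \text{opposite}\}$ within the promoter window,

$$ y_g = \alpha + \sum_{t,o} \beta_{t,o}\, x_{g,t,o} + \varepsilon_g, $$

fitted by ordinary least squares with two-sided t tests and
Benjamini–Hochberg FDR. A per-copy coefficient $\beta$ of 0.3 corresponds to
a $2^{0.3} \approx 1.23$-fold expression change per additional copy —
i.e. effects are additive in log2, multiplicative in ratio.

# Coordinate and window conventions

All intervals are held 0-based half-open internally; GTF and RepeatMasker
input (1-based closed) is converted at the I/O boundary, BED is native.
Overlap means at least one shared base. The promoter window is defined in
gene orientation: `upstream` bases 5' of the TSS and `downstream` bases
starting at the TSS, so on the `+` strand it is `[tss - up, tss + down)` and
on the `-` strand the exact mirror `[tss - down + 1, tss + up + 1)`; the TSS
base itself is inside the window exactly when `downstream >= 1`, identically
on both strands. The defaults are (2000, 0) for counting and enrichment,
(300, 50) for proximal motif scanning, and a 10 kb upstream window for
distance curves.

The TSS of a gene is the TSS of its highest-expressed transcript isoform
(mean over all samples; ties broken by lexicographically smallest transcript
id). When no transcript-level expression is available — the synthetic
generator emits gene-level expression only — the fallback is the outermost
(5'-most in gene orientation) TSS, which is deterministic and
strand-symmetric.

Counting is per repeat *record* (fragment): partial copies count, a repeat
overlapping two genes' promoters counts for both, and orientation is repeat
strand relative to the gene strand. Unstranded intervals (CpG islands, TFBS)
are counted in both orientations.

# Statistics

* **Cluster enrichment** — per (feature, cluster) a 2×2 table of presence
  (≥ 1 copy) in the cluster versus *all other clusters combined*, Pearson
  chi-square without continuity correction, Fisher's exact p substituted
  when any expected cell is below 5, BH FDR over all tests jointly.
* **t tests** are Welch's (unequal variance), two-sided, throughout; the
  dosage curve tests each adjacent pair of copy-number categories
  (0, 1, 2, 3, 4, ≥5).
* **Distance curves** assign genes by the nearest occurrence (optionally
  orientation-filtered) with genes lacking any occurrence as the reference
  category.
* **Rank bins** sort genes by fold-change (descending, ties by gene id) into
  consecutive groups; a trailing remainder is kept only when it is at least
  half a group. Bin correlation is the Pearson correlation between per-bin
  mean fold-change and per-bin carrier fraction, with the t-transform
  p-value on `n_bins - 2` df.
* **Multiple regression** drops rare features (fewer than 20 carrier genes
  by default) and zero-variance columns with a note, and resolves exact
  collinearity deterministically (columns processed in lexicographic order,
  the later duplicate dropped and named).
* **Gene-set over-representation** is the one-sided hypergeometric test.
* **Motif ANOVA** is a fixed-effects one-way ANOVA of per-gene maximal
  log-odds scores over fold-change-ranked groups — using the scores
  directly avoids an arbitrary binding-site cutoff. Site counts use a
  similarity threshold: a window counts at level τ when its log-odds score
  reaches τ times the maximal achievable score (τ = 0.9 by default);
  log-odds use background 0.25 per base and a pseudocount of 0.01 per cell.
  The alternative reading of "90% similarity" (positional identity) was
  considered and rejected as the default because score-fraction thresholds
  are the standard PWM practice.
* **Genome distribution** — per-type copy numbers are fitted as lognormal
  by MLE on natural-log counts (population SD); the KS goodness-of-fit p is
  flagged approximate because the parameters are estimated from the same
  data. Region assignment uses the repeat midpoint with precedence
  promoter > exon > intron > downstream > intergenic, so each copy gets one
  label; expected counts are proportional to effective (precedence-resolved)
  region lengths. Strand preference compares same/opposite counts against a
  50:50 null for repeats lying in the region of exactly one gene; repeats
  hitting genes on both strands are excluded.

# The synthetic generator

`sim_config()` defines the study conditions; `simulate_bundle()` emits a
complete bundle (annotation, repeats, expression, motifs, optional genome
sequence) plus ground truth, and `write_bundle()` serialises it in the same
formats the readers parse.

Defaults, chosen once as a scaled-down analogue of a mammalian promoter
landscape:

* one 10 Mb chromosome, 2000 genes, minimum TSS spacing 3 kb;
* six stages (zygote, early/mid/late 2C, 8C, blastocyst) × 4 samples;
* four gene archetypes — maternal decay, transient 2C, late activation,
  flat — mixed 0.3/0.2/0.3/0.2, with lognormal baselines
  (meanlog 3, sdlog 1) and per-sample lognormal noise of 0.8 log2 units;
* three repeat families: SINE-like (`B1_Sim`, 8×10⁻⁴ copies/bp ≈ 1.6
  expected copies per 2 kb promoter, β = 0.3 per copy on both strands,
  weak decay, scale 5 kb), LTR-like (`MT2_Sim`, 10⁻⁴ copies/bp, β = 1.2
  same-strand-only, sharp decay, scale 800 bp, placed with a same-strand
  bias of 0.8 toward the nearest gene) and LINE-like (`L1_Sim`, β = 0,
  depleted near TSSs: copies within 5 kb of a TSS retained with
  probability 0.3 — depletion rather than hard exclusion, because a
  completely absent family would make its null coefficient untestable).

Per-copy effects are applied at the *target* stage of each family's stage
pair, weighted by `w(d) = exp(-d / scale)` at the copy's upstream distance
to the TSS, within a 10 kb effect window, subject to the family's
orientation rule. Exponential decay is a one-parameter stand-in for the
qualitative observation that proximity matters and the effect fades by
5–7 kb; no functional form is claimed for real data.

**Effective coefficients.** A regression on raw counts inside the 2 kb
window does not estimate β itself but β times the mean decay weight of a
*counted* copy. Because copies are extended intervals, the nearest-base
distance of a counted copy has an atom at zero (copies spanning the
window's TSS edge) with mass `len / (W + len)`, giving

$$ \beta_\text{eff} = \beta\,\frac{\bar\ell + s\,(1 - e^{-W/s})}{W + \bar\ell} $$

with window `W`, decay scale `s` and mean copy length $\bar\ell$.
`truth.json` records both β and $\beta_\text{eff}$, and recovery is asserted
against the latter. Recovery analyses use pseudocount 0 in the fold-change
so the estimator matches the generator's additive-in-log2 model; the
user-facing default stays 1 expression unit as the conventional stabiliser
for real FPKM-like data.

What the generator deliberately does *not* emulate: read-level sampling
noise, overdispersed/clustered repeat placement, correlation between
archetype and repeat content, transcript isoform diversity, and sequence
homology between repeat copies (consensus sequences are planted exactly;
their backgrounds are G/C-only so the planted motif count is exact by
construction). Passing tests therefore demonstrate that the *estimators*
are correct and calibrated under a known model, not that real embryonic
data satisfies that model.

# Verification conditions and problem sizes

* Kernel oracles: interval overlap on 10⁴ random queries against exhaustive
  scan; feature tables on 500 windows × 2000 repeats against a per-pair
  tally; PWM scores on 100 random sequence/matrix pairs against
  per-window evaluation.
* Parameter recovery: 100 seeds of the default 2000-gene configuration;
  each planted nonzero coefficient must fall inside its 95% CI in ≥ 90% of
  seeds with the correct sign, planted-null coefficients must exceed FDR
  0.1 in ≥ 90% of seeds; a noise-free single-family, single-archetype,
  no-decay configuration must recover β to machine precision.
* Qualitative signatures (default configuration, seed 1): strictly
  monotone SINE dosage curve; LTR same-strand coefficient significant at
  FDR < 0.05 with the opposite-strand coefficient above it;
  same-strand-nearest distance curve significant in the first kilobase and
  flat beyond the planted scale.
* Bin correlation: the "strong planted effect" condition is instantiated
  as 24 bins of 500 genes (12 000 genes on 50 Mb), per-copy effect at the
  top of the plausible per-element range (40% per copy, β = log2 1.4), and
  a flat archetype background so that the dosage effect is the dominant
  systematic fold-change signal. Under the default archetype mixture most
  fold-change variance is archetype-driven and independent of repeat
  content by construction, so no per-copy effect of realistic size is
  "strong" relative to it; the measured bin PCC there is ≈ 0.8.
* Type-I control: 10⁴ Welch tests with features permuted against
  fold-change (5% ± 1%), 1000 null strand-preference simulations and 1250
  permuted adjacent-dosage tests (± 2%).

These sizes keep the full test suite and the acceptance script each within
a few minutes on one CPU while leaving the binomial error of the rate
checks well below their tolerance bands.

# Known limitations

* Fragment-level counting means a single insertion split by RepeatMasker
  into several records counts several times; join-by-ID is available at
  parse time but is not the default, matching the partial-element counting
  the analyses assume.
* The KS p-value for the lognormal fit is anti-conservative (estimated
  parameters); it is reported for description, not inference.
* `hclust` average linkage resolves distance ties by merge order; the
  package canonicalises input order (rows sorted by name) so results are
  reproducible, but tie-heavy matrices remain sensitive to the distance
  values themselves.
* The ortholog analysis assumes a 1:1 pair table; paralog expansion is out
  of scope.
* Regression inference is OLS with homoskedastic errors; per-copy effect
  heterogeneity adds mild count-dependent variance that the SEs ignore
  (negligible at the default effect sizes).
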