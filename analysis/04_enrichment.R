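#!/usr/bin/env Rscript
# Step 4: enrichment of repeats in gene clusters and rank bins.
#
# Chi-square enrichment of promoter repeat presence in each temporal gene
# cluster against all other clusters combined; Welch presence tests against
# the late-2C fold-change; and the bin-level correlation between mean
# fold-change and repeat prevalence across the 24 rank bins.

suppressMessages({library(teprom); library(data.table)})

ft <- read_tsv("results/promoter_features_2kb.tsv")
clusters <- read_tsv("results/gene_clusters.tsv")
fc <- read_tsv("results/fold_change_mid2C_late2C.tsv")
bins <- read_tsv("results/rank_bins.tsv")

any_cols <- grep("^count.*[.]any$", names(ft), value = TRUE)
feat <- as.matrix(ft[, any_cols, with = FALSE])
rownames(feat) <- ft$gene_id
colnames(feat) <- sub("^count[.]name[.]", "", sub("[.]any$", "", any_cols))

cl <- setNames(clusters$cluster, clusters$gene_id)
enr <- cluster_enrichment(feat > 0, cl)
write_tsv(enr, "results/cluster_enrichment.tsv")
top <- enr[order(fdr)][1:5]
cat("strongest cluster enrichments:\n")
print(top[, c("feature", "cluster", "fold_enrichment", "chi2", "fdr")])

pres <- presence_fc_test(feat > 0, fc)
write_tsv(pres, "results/presence_fc_tests.tsv")
cat("\npresence vs fold-change (Welch):\n")
print(pres[, c("feature", "diff", "t", "fdr")])

for (nm in colnames(feat)) {
  bc <- bin_correlation(bins, setNames(as.integer(feat[, nm] > 0),
                                       rownames(feat)))
  cat(sprintf("\nbin correlation, %s: PCC = %.3f (p = %.2g, %d bins)\n",
              nm, bc$pcc, bc$p, bc$n_bins))
  write_tsv(bc$per_bin, sprintf("results/bin_correlation_%s.tsv", nm))
}
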