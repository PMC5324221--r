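#!/usr/bin/env Rscript
# Step 5: dosage curves, distance curves, the multiple regression, and
# per-sample expression-count correlation.
#
# The dosage curve bins genes by SINE-like copy number (>= 5 pooled); the
# distance curve tracks the same-strand LTR effect by nearest distance to
# the TSS; the orientation-split multiple regression estimates per-copy
# effects jointly; and the per-sample correlation of expression with SINE
# counts traces the association across development.

suppressMessages({library(teprom); library(data.table)})

ft <- read_tsv("results/promoter_features_2kb.tsv")
fc_late <- read_tsv("results/fold_change_mid2C_late2C.tsv")
fc_mid <- read_tsv("results/fold_change_early2C_mid2C.tsv")
nearest <- read_tsv("results/nearest_mt2_same_strand.tsv")
expr <- read_expression("results/sim/expression.tsv", "results/sim/design.tsv")

cnt <- setNames(ft$count.name.B1_Sim.any, ft$gene_id)
da <- dosage_analysis(cnt, fc_late, cap = 5)
write_tsv(da, "results/dosage_curve_B1_Sim.tsv")
cat("SINE-like dosage curve (mean log2 FC by promoter copy number):\n")
print(da[, c("category", "n_genes", "mean_log2fc", "se", "stars")])

dd <- distance_analysis(setNames(nearest$nearest.MT2_Sim, nearest$gene_id),
                        fc_mid, edges = c(0, 1000, 2000, 4000, 7000, 10000))
write_tsv(dd, "results/distance_curve_MT2_Sim.tsv")
cat("\nLTR-like distance curve (same-strand nearest copy):\n")
print(dd[, c("category", "n_genes", "diff_vs_none", "p_vs_none", "stars")])

X <- as.matrix(ft[, grep("[.](same|opposite)$", names(ft)), with = FALSE])
rownames(X) <- ft$gene_id
reg_late <- multiple_regression(fc_late, X, min_genes = 5)
reg_mid <- multiple_regression(fc_mid, X, min_genes = 5)
write_tsv(reg_late, "results/regression_mid2C_late2C.tsv")
write_tsv(reg_mid, "results/regression_early2C_mid2C.tsv")
cat("\nper-copy regression, early2C -> mid2C (LTR target):\n")
print(reg_mid)
cat("\nper-copy regression, mid2C -> late2C (SINE target):\n")
print(reg_late)

ecc <- expression_count_correlation(expr, cnt)
write_tsv(ecc, "results/expression_count_correlation.tsv")
stage_pcc <- ecc[, list(mean_pcc = mean(pcc)), by = "stage"]
cat("\nmean per-stage correlation of expression with SINE-like counts:\n")
print(stage_pcc)
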