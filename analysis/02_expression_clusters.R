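#!/usr/bin/env Rscript
# Step 2: expression filtering, stage fold-changes and gene/sample grouping.
#
# Filters genes (max expression >= 5, most-variable kept), computes the two
# stage fold-changes the planted effects target, defines temporal gene
# clusters by hierarchical clustering (1 - Pearson, average linkage), rank
# bins of the late-2C fold-change, and splits blastocyst-stage samples into
# subtypes.

suppressMessages({library(teprom); library(data.table)})

expr <- read_expression("results/sim/expression.tsv", "results/sim/design.tsv")

keep <- filter_genes(expr, min_level = 5, top_n = 12000L)
cat("genes passing the expression filter:", length(keep), "of",
    nrow(expr$mat), "\n")

fc_late <- fold_change(expr, "mid2C", "late2C", pseudocount = 0, genes = keep)
fc_mid <- fold_change(expr, "early2C", "mid2C", pseudocount = 0, genes = keep)
write_tsv(fc_late, "results/fold_change_mid2C_late2C.tsv")
write_tsv(fc_mid, "results/fold_change_early2C_mid2C.tsv")

hc <- hierarchical_cluster(expr$mat[keep, ], k = 10)
clusters <- data.table(gene_id = names(hc$labels), cluster = hc$labels)
write_tsv(clusters, "results/gene_clusters.tsv")
cat("hierarchical cluster sizes (k=10):",
    paste(sort(table(hc$labels), decreasing = TRUE), collapse = " "), "\n")

bins <- rank_bins(fc_late, group_size = 83L)  # 24 bins over 2000 genes
write_tsv(bins, "results/rank_bins.tsv")
cat("rank bins:", max(bins$bin), "of", attr(bins, "remainder_kept"), "\n")

blast <- expr$design$sample[expr$design$stage == "blast"]
sub <- split_sample_types(
  expr_set(expr$mat[keep, blast], expr$design[expr$design$sample %in% blast]),
  k = 3)
write_tsv(data.table(sample = names(sub), subtype = sub),
          "results/blastocyst_subtypes.tsv")
cat("blastocyst subtype sizes:", paste(table(sub), collapse = " "), "\n")
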