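#!/usr/bin/env Rscript
# Step 3: promoters and the per-gene repeat feature tables.
#
# Selects one TSS per gene, builds the 2 kb upstream counting window and a
# 10 kb window for distance analyses, and tabulates per-gene repeat counts
# split by orientation, family coverage, and nearest same-strand LTR
# distance.

suppressMessages({library(teprom); library(data.table)})

tx <- read_gtf("results/sim/genes.gtf")
repeats <- read_repeatmasker("results/sim/repeats.out")
contigs <- c(chrS = 1e7)

tss <- select_tss(tx)
prom <- make_promoters(tss, upstream = 2000, downstream = 0, contigs)
write_bed(data.table(chrom = prom$chrom, start = prom$start, end = prom$end,
                     name = prom$gene_id, score = 0L, strand = prom$strand),
          "results/promoters_2kb.bed")

ft <- build_feature_table(prom, repeats, level = "name")
write_tsv(ft, "results/promoter_features_2kb.tsv")
cat("2 kb feature table:", nrow(ft), "genes x", ncol(ft) - 1, "features\n")
frac <- colMeans(ft[, grep("[.]any$", names(ft)), with = FALSE] > 0)
cat("fraction of genes with >= 1 copy:\n")
print(round(frac, 3))

wide <- make_promoters(tss, upstream = 10000, downstream = 0, contigs)
ftw <- build_feature_table(wide, repeats, level = "name",
                           coverage_families = character(0),
                           distance_names = "MT2_Sim",
                           distance_orientation = "same")
write_tsv(ftw[, c("gene_id", "nearest.MT2_Sim"), with = FALSE],
          "results/nearest_mt2_same_strand.tsv")
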