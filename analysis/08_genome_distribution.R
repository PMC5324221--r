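#!/usr/bin/env Rscript
# Step 8: genome-wide repeat distribution statistics.
#
# Copy-number lognormal fit across repeat types, inter-repeat distance
# histograms, region enrichment under the promoter > exon > intron >
# downstream > intergenic precedence, and strand preference of repeats
# inside promoters and gene bodies.

suppressMessages({library(teprom); library(data.table)})

repeats <- read_repeatmasker("results/sim/repeats.out")
tx <- read_gtf("results/sim/genes.gtf")
tss <- select_tss(tx)
contigs <- c(chrS = 1e7)

fit <- copy_number_fit(repeats)
cat(sprintf("copy-number lognormal fit over %d types: mu=%.2f sigma=%.2f (KS p=%.3f, approximate)\n",
            fit$n_types, fit$mu, fit$sigma, fit$ks_p))

for (nm in unique(repeats$name)) {
  ird <- inter_repeat_distances(repeats, nm)
  cat(sprintf("inter-repeat distances, %-8s n=%5d log-log slope=%.2f\n",
              nm, length(ird$distances), ird$loglog_slope))
  write_tsv(ird$histogram, sprintf("results/interdistance_%s.tsv", nm))
}

m <- region_model(tx, tss, contigs)
re <- region_enrichment(repeats, m, level = "klass")
write_tsv(re, "results/region_enrichment.tsv")
cat("\nregion enrichment (fold = observed / length-expected):\n")
print(dcast(re, feature ~ region, value.var = "fold"))

sp_prom <- strand_preference(repeats, m$promoter)
sp_gene <- strand_preference(repeats, m$intron)  # gene spans
write_tsv(sp_prom, "results/strand_preference_promoter.tsv")
write_tsv(sp_gene, "results/strand_preference_genebody.tsv")
cat("\nstrand preference in promoters (same:opposite, chi-square vs 50:50):\n")
print(sp_prom)
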