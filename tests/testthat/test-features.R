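simple_prom <- function() {
  data.table::data.table(gene_id = "g1", chrom = "chr1", strand = "+",
                         start = 8000L, end = 10000L, tss = 10000L,
                         clipped = FALSE)
}

rep_dt <- function(starts, ends, strands, name = "R1", family = "FamA",
                   klass = "K", chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = as.integer(starts),
                         end = as.integer(ends), strand = strands,
                         name = name, family = family, klass = klass)
}

test_that("counts and coverage follow the overlap arithmetic", {
  # two disjoint 100 bp repeats fully inside a 2000 bp window
  reps <- rep_dt(c(8100, 8500), c(8200, 8600), c("+", "-"))
  ft <- build_feature_table(simple_prom(), reps, level = "family")
  expect_equal(ft$count.family.FamA.any, 2L)
  expect_equal(ft$count.family.FamA.same, 1L)
  expect_equal(ft$count.family.FamA.opposite, 1L)
  expect_equal(ft$coverage.FamA, 0.10)
})

test_that("a promoter chromosome absent from the repeats warns and zero-fills", {
  reps <- rep_dt(100, 200, "+", chrom = "chr9")
  expect_warning(ft <- build_feature_table(simple_prom(), reps, level = "name"),
                 "absent")
  expect_equal(ft$count.name.R1.any, 0L)
  expect_equal(ft$coverage.FamA, 0)
})

test_that("counts of any orientation equal same plus opposite", {
  set.seed(3)
  b <- simulate_bundle(small_config())
  prom <- make_promoters(b$tss, 2000, 0, b$contig_lengths)
  ft <- build_feature_table(prom, b$repeats, level = "name",
                            coverage_families = character(0))
  for (nm in unique(b$repeats$name)) {
    expect_equal(ft[[paste0("count.name.", nm, ".any")]],
                 ft[[paste0("count.name.", nm, ".same")]] +
                   ft[[paste0("count.name.", nm, ".opposite")]])
  }
})

test_that("feature counts match a brute-force per-pair overlap tally", {
  set.seed(21)
  n_w <- 120; n_r <- 600
  tssmap <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:n_w), chrom = "c1",
    strand = sample(c("+", "-"), n_w, TRUE),
    tss = sort(sample(5000:995000, n_w)))
  prom <- make_promoters(tssmap, 2000, 0, c(c1 = 1e6))
  starts <- sample.int(999000, n_r)
  reps <- rep_dt(starts, starts + sample.int(800, n_r, TRUE),
                 sample(c("+", "-"), n_r, TRUE),
                 name = sample(c("A", "B", "C"), n_r, TRUE), chrom = "c1")
  ft <- build_feature_table(prom, reps, level = "name",
                            coverage_families = character(0))
  for (i in sample.int(nrow(prom), 40)) {
    hit <- bf_overlaps(reps$start, reps$end, prom$start[i], prom$end[i])
    for (nm in c("A", "B", "C")) {
      expect_equal(ft[[paste0("count.name.", nm, ".any")]][i],
                   sum(hit & reps$name == nm))
      expect_equal(ft[[paste0("count.name.", nm, ".same")]][i],
                   sum(hit & reps$name == nm & reps$strand == prom$strand[i]))
    }
  }
})

test_that("shrinking the window never increases counts or covered bases", {
  set.seed(5)
  b <- simulate_bundle(small_config())
  prom_big <- make_promoters(b$tss, 4000, 500, b$contig_lengths)
  prom_small <- make_promoters(b$tss, 2000, 0, b$contig_lengths)
  big <- build_feature_table(prom_big, b$repeats, level = "family")
  small <- build_feature_table(prom_small, b$repeats, level = "family")
  ib <- match(big$gene_id, small$gene_id)
  len_big <- prom_big$end - prom_big$start
  len_small <- (prom_small$end - prom_small$start)[ib]
  for (col in grep("^count", names(big), value = TRUE)) {
    expect_true(all(small[[col]][ib] <= big[[col]]))
  }
  # coverage is a window fraction; monotone in covered base pairs
  for (col in grep("^coverage", names(big), value = TRUE)) {
    expect_true(all(small[[col]][ib] * len_small <= big[[col]] * len_big + 1e-9))
  }
})

test_that("feature table is invariant to repeat record order", {
  set.seed(6)
  b <- simulate_bundle(small_config())
  prom <- make_promoters(b$tss, 2000, 0, b$contig_lengths)
  shuffled <- b$repeats[sample.int(nrow(b$repeats))]
  expect_equal(build_feature_table(prom, b$repeats, level = "name"),
               build_feature_table(prom, shuffled, level = "name"))
})

test_that("merged coverage never exceeds the sum of unmerged fractions", {
  # overlapping repeats of one family
  reps <- rep_dt(c(8100, 8150, 9000), c(8300, 8400, 9100), c("+", "+", "+"))
  ft <- build_feature_table(simple_prom(), reps, level = "family")
  unmerged <- sum(pmin(reps$end, 10000) - pmax(reps$start, 8000)) / 2000
  expect_equal(ft$coverage.FamA, ((8400 - 8100) + 100) / 2000)
  expect_lte(ft$coverage.FamA, unmerged)
})

test_that("CpG islands, TFBS and dinucleotide counts populate the table", {
  cpg <- data.table::data.table(chrom = "chr1", start = 8500L, end = 8700L,
                                strand = ".")
  tfbs <- data.table::data.table(chrom = "chr1",
                                 start = c(8100L, 8200L, 9500L),
                                 end = c(8110L, 8210L, 9510L),
                                 name = c("Myc", "Myc", "E2f1"))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 5000),
                                                    collapse = "")))
  ft <- build_feature_table(simple_prom(), rep_dt(8100, 8200, "+"),
                            level = "name", cpg_intervals = cpg,
                            tfbs_intervals = tfbs, genome = genome)
  expect_equal(ft$cpg_island_count, 1L)
  expect_equal(ft$cpg_island_coverage, 0.1)
  expect_equal(ft$tfbs_count.Myc, 2L)
  expect_equal(ft$tfbs_count.E2f1, 1L)
  # "ACGT" repeated: no CG dinucleotide spans positions 8000..9999? The
  # sequence is A C G T A C G T ...; "CG" occurs at each C followed by G,
  # i.e. once per 4-mer = 500 in 2000 bp
  expect_equal(ft$cpg_dinucleotide_count, 500L)
})

test_that("dosage binning caps the top category and rejects negatives", {
  expect_equal(as.character(dosage_bin(c(0, 1, 4, 5, 7))),
               c("0", "1", "4", ">=5", ">=5"))
  expect_error(dosage_bin(-1L), "negative")
  # bin occupancies on a fixture match a hand tally
  counts <- c(0, 0, 0, 1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 9, 0, 1, 2, 3, 5, 5)
  tab <- table(dosage_bin(counts))
  expect_equal(unname(as.integer(tab)),
               c(4L, 3L, 4L, 2L, 2L, 5L))
})

test_that("distance bins are right-open with zero in the first bin", {
  edges <- c(0, 1000, 2000)
  b <- distance_bins(c(0, 999, 1000, 1999, 2000, NA), edges)
  expect_equal(as.character(b),
               c("[0,1000)", "[0,1000)", "[1000,2000)", "[1000,2000)", NA, NA))
  # bin counts on a random fixture match enumeration
  set.seed(9)
  d <- sample(0:2500, 50, TRUE)
  got <- table(distance_bins(d, edges))
  expect_equal(unname(as.integer(got)),
               c(sum(d >= 0 & d < 1000), sum(d >= 1000 & d < 2000)))
})
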