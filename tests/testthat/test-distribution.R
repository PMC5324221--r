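test_that("lognormal copy-number fit matches the hand MLE", {
  fit <- copy_number_fit(c(1, exp(2), exp(4)))
  expect_equal(fit$mu, 2)
  expect_equal(fit$sigma, sqrt(8 / 3))
  # all counts equal: mu = ln c, sigma = 0
  fit0 <- copy_number_fit(rep(7, 5))
  expect_equal(fit0$mu, log(7))
  expect_equal(fit0$sigma, 0)
})

test_that("lognormal fit recovers sampling parameters and is scale-equivariant", {
  set.seed(41)
  x <- stats::rlnorm(1e4, meanlog = 2, sdlog = 1)
  fit <- copy_number_fit(x)
  expect_lt(abs(fit$mu - 2), 0.05)
  expect_lt(abs(fit$sigma - 1), 0.05)
  fit_scaled <- copy_number_fit(x * 10)
  expect_equal(fit_scaled$mu, fit$mu + log(10), tolerance = 1e-12)
  expect_equal(fit_scaled$sigma, fit$sigma, tolerance = 1e-12)
  expect_true(fit$ks_p_approximate)
})

test_that("inter-repeat distances are per chromosome consecutive-start gaps", {
  reps <- data.table::data.table(
    chrom = c("c1", "c1", "c2", "c2", "c2", "c3"),
    start = c(100L, 350L, 10L, 500L, 600L, 42L),
    end = c(150L, 400L, 60L, 550L, 650L, 92L),
    strand = "+", name = "R", family = "F", klass = "K")
  res <- inter_repeat_distances(reps, "R")
  expect_equal(sort(res$distances), c(100L, 250L, 490L))
  # a single repeat on a chromosome contributes no distance
  res1 <- inter_repeat_distances(reps[reps$chrom == "c3"], "R")
  expect_equal(length(res1$distances), 0L)
})

test_that("clustered placement yields a steeper distance-histogram tail than uniform", {
  set.seed(43)
  n <- 3000
  uni <- sort(sample.int(3e6, n))
  centers <- sample.int(3e6, 60)
  clus <- sort(pmin(pmax(rep(centers, each = n / 60) +
                           round(stats::rnorm(n, sd = 2000)), 1), 3e6))
  mk <- function(st) data.table::data.table(
    chrom = "c1", start = as.integer(st), end = as.integer(st + 10),
    strand = "+", name = "R", family = "F", klass = "K")
  s_uni <- inter_repeat_distances(mk(uni), "R")$loglog_slope
  s_clu <- inter_repeat_distances(mk(clus), "R")$loglog_slope
  expect_lt(s_clu, s_uni)
})

test_that("region classification follows the stated precedence by midpoint", {
  tx <- data.table::data.table(
    transcript_id = "t1", gene_id = "g1", chrom = "c1", strand = "+",
    start = 10000L, end = 16000L, tss = 10000L,
    exon_starts = list(c(10000L, 15000L)), exon_ends = list(c(11000L, 16000L)))
  tssmap <- data.table::data.table(gene_id = "g1", chrom = "c1",
                                   strand = "+", tss = 10000L)
  m <- region_model(tx, tssmap, c(c1 = 50000L), promoter_upstream = 2000L,
                    downstream_bp = 2000L)
  expect_equal(teprom:::classify_positions(m, "c1",
                                  c(9000L, 10500L, 12000L, 16500L, 30000L)),
               c("promoter", "exon", "intron", "downstream", "intergenic"))
  # effective lengths partition the genome
  expect_equal(sum(m$region_lengths), 50000)
  expect_equal(unname(m$region_lengths["promoter"]), 2000)
  expect_equal(unname(m$region_lengths["intron"]), 4000)
})

test_that("region enrichment fold matches hand arithmetic on a two-region toy", {
  tx <- data.table::data.table(
    transcript_id = "t1", gene_id = "g1", chrom = "c1", strand = "+",
    start = 5000L, end = 10000L, tss = 5000L,
    exon_starts = list(5000L), exon_ends = list(10000L))
  tssmap <- data.table::data.table(gene_id = "g1", chrom = "c1",
                                   strand = "+", tss = 5000L)
  m <- region_model(tx, tssmap, c(c1 = 20000L), promoter_upstream = 5000L,
                    downstream_bp = 0L)
  # regions: promoter 5000, exon 5000, intergenic 10000
  mids <- c(2000L, 7000L, 7500L, 15000L)
  reps <- data.table::data.table(chrom = "c1", start = mids - 5L,
                                 end = mids + 5L, strand = "+",
                                 name = "R", family = "F", klass = "K")
  res <- region_enrichment(reps, m, level = "name")
  ex_row <- res[res$region == "exon"]
  # 2 of 4 observed in the exon region vs expected 4 * (5000/20000) = 1
  expect_equal(ex_row$n_exp, 1)
  expect_equal(ex_row$fold, 2)
  # length-weighted average fold is 1 (conservation)
  lens <- m$region_lengths[res$region]
  expect_equal(sum(res$fold * lens / sum(m$region_lengths)), 1,
               tolerance = 1e-12)
})

test_that("uniform random placement shows no region enrichment", {
  set.seed(44)
  b <- simulate_bundle(small_config())
  m <- region_model(b$transcripts, b$tss, b$contig_lengths)
  st <- sort(sample.int(1950000, 800))
  reps <- data.table::data.table(chrom = "chrS", start = st, end = st + 100L,
                                 strand = sample(c("+", "-"), 800, TRUE),
                                 name = "U", family = "U", klass = "U")
  res <- region_enrichment(reps, m, level = "name")
  expect_true(all(abs(res$fold - 1) < 0.35))
  expect_gt(mean(res$p > 0.05), 0.7)
})

test_that("strand preference reproduces the ratio arithmetic and detects planted bias", {
  set.seed(45)
  # 56 repeats in one gene's span: 46 same, 10 opposite -> ratio 4.6
  genes <- data.table::data.table(chrom = "c1", start = 0L, end = 60000L,
                                  strand = "+", gene_id = "g1")
  st <- seq(100L, by = 1000L, length.out = 56L)
  reps <- data.table::data.table(
    chrom = "c1", start = st, end = st + 100L,
    strand = c(rep("+", 46), rep("-", 10)),
    name = "R", family = "F", klass = "K")
  res <- strand_preference(reps, genes)
  expect_equal(res$n_same, 46L)
  expect_equal(res$n_opposite, 10L)
  expect_equal(res$ratio, 4.6)
  expect_equal(res$chi2, (46 - 28)^2 / 28 + (10 - 28)^2 / 28)
  # flipping every strand simultaneously leaves the result unchanged
  flip <- function(s) ifelse(s == "+", "-", "+")
  reps2 <- data.table::copy(reps)[, "strand" := flip(strand)]
  genes2 <- data.table::copy(genes)[, "strand" := flip(strand)]
  expect_equal(strand_preference(reps2, genes2), res)
  # planted 4:1 bias at n = 200 is detected overwhelmingly
  reps3 <- data.table::data.table(
    chrom = "c1", start = seq(1L, by = 250L, length.out = 200L),
    end = seq(1L, by = 250L, length.out = 200L) + 50L,
    strand = c(rep("+", 160), rep("-", 40)),
    name = "R", family = "F", klass = "K")
  expect_lt(strand_preference(reps3, genes)$p, 1e-6)
})

test_that("repeats spanning genes on both strands are excluded", {
  genes <- data.table::data.table(
    chrom = "c1", start = c(0L, 5000L), end = c(10000L, 20000L),
    strand = c("+", "-"), gene_id = c("g1", "g2"))
  reps <- data.table::data.table(
    chrom = "c1", start = c(6000L, rep(12000L, 11)),
    end = c(6100L, rep(12100L, 11)),
    strand = "+", name = "R", family = "F", klass = "K")
  res <- strand_preference(reps, genes, min_total = 10)
  # the overlap-ambiguous repeat at 6000 is dropped; the 11 others sit in g2
  expect_equal(res$n_same + res$n_opposite, 11L)
})
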