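test_that("cluster enrichment reproduces hand-computed chi-square and fold", {
  # 100 genes in the cluster (30 carriers), 100 outside (10 carriers):
  # expected cells 20/80/20/80 give chi2 = 12.5, fold = 3
  feat <- matrix(c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)), ncol = 1,
                 dimnames = list(sprintf("g%03d", 1:200), "F"))
  cl <- stats::setNames(rep(c("in", "out"), each = 100), rownames(feat))
  res <- cluster_enrichment(feat, cl)
  row <- res[res$cluster == "in"]
  expect_equal(row$chi2, 12.5)
  expect_equal(row$fold_enrichment, 3)
  expect_equal(row$method, "chisq")
  # identical fractions in and out: chi2 = 0, fold = 1, p = 1
  feat2 <- matrix(rep(c(1, 0), 100), ncol = 1,
                  dimnames = list(rownames(feat), "F"))
  res2 <- cluster_enrichment(feat2, cl)
  expect_equal(res2$chi2, c(0, 0))
  expect_equal(res2$fold_enrichment, c(1, 1))
  expect_equal(res2$p, c(1, 1))
})

test_that("Fisher's exact test replaces chi-square at small expected counts", {
  feat <- matrix(c(rep(1, 3), rep(0, 17), rep(1, 1), rep(0, 79)), ncol = 1,
                 dimnames = list(sprintf("g%03d", 1:100), "F"))
  cl <- stats::setNames(rep(c("a", "b"), c(20, 80)), rownames(feat))
  res <- cluster_enrichment(feat, cl)
  expect_true(all(res$method == "fisher"))
  expect_equal(res[res$cluster == "a"]$p,
               stats::fisher.test(rbind(c(3, 17), c(1, 79)))$p.value)
})

test_that("BH adjustment matches the hand-stepped fixture", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  # via a battery result: fdr is monotone non-decreasing in ranked p
  set.seed(2)
  feat <- matrix(rbinom(500 * 5, 1, 0.4), ncol = 5,
                 dimnames = list(sprintf("g%03d", 1:500), paste0("F", 1:5)))
  fc <- data.table::data.table(gene_id = rownames(feat), log2fc = rnorm(500))
  res <- presence_fc_test(feat, fc)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("presence t-test is Welch's and flags degenerate variance", {
  a <- c(2.1, 3.4, 1.2, 4.4, 2.8)
  b <- c(0.3, 1.1, 0.9)
  feat <- matrix(c(rep(1, 5), rep(0, 3)), ncol = 1,
                 dimnames = list(paste0("g", 1:8), "F"))
  fc <- data.table::data.table(gene_id = paste0("g", 1:8), log2fc = c(a, b))
  res <- presence_fc_test(feat, fc)
  # hand Welch statistic
  tt <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 3)
  expect_equal(res$t, tt)
  expect_equal(res$p, stats::t.test(a, b)$p.value)
  # zero-variance groups are flagged, difference still reported
  fc0 <- data.table::data.table(gene_id = paste0("g", 1:8),
                                log2fc = c(rep(1, 5), rep(0, 3)))
  res0 <- presence_fc_test(feat, fc0)
  expect_true(res0$degenerate)
  expect_equal(res0$diff, 1)
  # identical groups: p = 1, diff = 0
  fci <- data.table::data.table(gene_id = paste0("g", 1:8),
                                log2fc = c(1, 2, 3, 1, 3, 1, 2, 3))
  resi <- presence_fc_test(feat, fci)
  expect_equal(resi$diff, 0)
  expect_gt(resi$p, 0.9)
})

test_that("noise-free dosage curve reproduces the planted per-copy means", {
  beta <- 0.4
  counts <- stats::setNames(rep(0:6, each = 10), sprintf("g%02d", 1:70))
  fc <- data.table::data.table(gene_id = names(counts),
                               log2fc = beta * counts)
  res <- dosage_analysis(counts, fc, cap = 5)
  expect_equal(res$mean_log2fc[1:5], beta * (0:4))
  expect_equal(res$mean_log2fc[6], beta * mean(c(5, 6)))
  expect_equal(res$category, c("0", "1", "2", "3", "4", ">=5"))
  # an empty bin is reported missing, without a test
  counts2 <- stats::setNames(c(0, 0, 2, 2, 5, 5), paste0("h", 1:6))
  fc2 <- data.table::data.table(gene_id = names(counts2), log2fc = rnorm(6))
  res2 <- dosage_analysis(counts2, fc2)
  expect_equal(res2$n_genes[res2$category == "1"], 0L)
  expect_true(is.na(res2$mean_log2fc[res2$category == "1"]))
  expect_true(is.na(res2$p_vs_prev[res2$category == "1"]))
})

test_that("distance curve honours half-open edges and uses no-repeat genes as reference", {
  set.seed(30)
  nearest <- stats::setNames(c(0, 500, 1000, 1500, NA, NA, NA, NA),
                             paste0("g", 1:8))
  fc <- data.table::data.table(gene_id = paste0("g", 1:8),
                               log2fc = c(2, 2, 1, 1, 0.1, -0.1, 0.05, -0.05))
  res <- distance_analysis(nearest, fc, edges = c(0, 1000, 2000))
  expect_equal(res$n_genes, c(2L, 2L, 4L))
  expect_equal(res$mean_log2fc, c(2, 1, 0))
  expect_equal(res$diff_vs_none, c(2, 1, 0))
})

test_that("bin correlation is 1 for an exactly linear relation and flags constants", {
  bins <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:144),
    log2fc = rep(seq(12, 1), each = 12) + rep(seq(0, 0.55, 0.05), 12),
    bin = rep(1:12, each = 12))
  # bin b holds 13 - b carriers of 12 genes, so the carrier fraction is an
  # exactly linear function of the bin mean fold-change
  feat <- stats::setNames(unlist(lapply(1:12, function(b) {
    rep(c(1L, 0L), c(13L - b, b - 1L))
  })), bins$gene_id)
  res <- bin_correlation(bins, feat)
  expect_equal(res$pcc, 1, tolerance = 1e-9)
  # constant fraction: undefined, flagged
  res2 <- bin_correlation(bins, stats::setNames(rep(1, 144), bins$gene_id))
  expect_true(res2$degenerate)
  expect_true(is.na(res2$pcc))
  expect_error(bin_correlation(bins[bins$bin <= 2], feat), ">= 3")
})

test_that("regression solves the noise-free system exactly and drops duplicates", {
  set.seed(17)
  n <- 200
  x1 <- rpois(n, 2); x2 <- rpois(n, 1)
  X <- cbind(a_x1 = x1, b_x2 = x2)
  rownames(X) <- sprintf("g%03d", 1:n)
  fc <- data.table::data.table(gene_id = rownames(X),
                               log2fc = 0.3 * x1 + 0.1 * x2)
  res <- multiple_regression(fc, X, min_genes = 1)
  expect_equal(stats::setNames(res$estimate, res$feature),
               c(a_x1 = 0.3, b_x2 = 0.1), tolerance = 1e-10)
  expect_equal(attr(res, "r_squared"), 1, tolerance = 1e-10)
  # a duplicated column is dropped deterministically and named
  X2 <- cbind(X, c_dup = x1)
  expect_warning(res2 <- multiple_regression(fc, X2, min_genes = 1), "c_dup")
  expect_false("c_dup" %in% res2$feature)
  expect_true(all(c("a_x1", "b_x2") %in% res2$feature))
})

test_that("expression-count correlation finds planted linear relations and partials itself out", {
  set.seed(19)
  n <- 300
  counts <- stats::setNames(rpois(n, 2), sprintf("g%03d", 1:n))
  mat <- cbind(s1 = 2^(0.5 * counts + rnorm(n, sd = 1e-8)),
               s2 = 2^rnorm(n))
  rownames(mat) <- names(counts)
  ex <- make_expr(mat, c("a", "a"))
  res <- expression_count_correlation(ex, counts, pseudocount = 0)
  expect_equal(res$pcc[res$sample == "s1"], 1, tolerance = 1e-6)
  expect_lt(abs(res$pcc[res$sample == "s2"]), 3 / sqrt(n))
  # partialling out the count itself gives ~0
  resp <- expression_count_correlation(ex, counts, pseudocount = 0,
                                       control = counts)
  expect_equal(resp$pcc[resp$sample == "s1"], 0, tolerance = 1e-4)
})

test_that("ortholog association recovers identity and rejects empty pair lists", {
  counts_a <- stats::setNames(c(3, 1, 4, 1, 5, 9, 2, 6), paste0("a", 1:8))
  counts_b <- stats::setNames(c(3, 1, 4, 1, 5, 9, 2, 6) + 0, paste0("b", 1:8))
  pairs <- data.table::data.table(gene_a = paste0("a", 1:8),
                                  gene_b = paste0("b", 1:8))
  fc_a <- data.table::data.table(gene_id = paste0("a", 1:8), log2fc = rnorm(8))
  fc_b <- data.table::data.table(gene_id = paste0("b", 1:8), log2fc = rnorm(8))
  res <- ortholog_delta_association(pairs, counts_a, counts_b, fc_a, fc_b)
  expect_equal(res$count_pcc, 1)
  expect_error(ortholog_delta_association(
    data.table::data.table(gene_a = "zz", gene_b = "yy"),
    counts_a, counts_b, fc_a, fc_b), "empty")
})

test_that("ortholog delta regression recovers a planted shared effect", {
  set.seed(23)
  n <- 500
  ca <- rpois(n, 2); cb <- rpois(n, 2)
  beta <- 0.5
  fa <- beta * ca + rnorm(n, sd = 0.3)
  fb <- beta * cb + rnorm(n, sd = 0.3)
  pairs <- data.table::data.table(gene_a = sprintf("a%03d", 1:n),
                                  gene_b = sprintf("b%03d", 1:n))
  res <- ortholog_delta_association(
    pairs,
    stats::setNames(ca, pairs$gene_a), stats::setNames(cb, pairs$gene_b),
    data.table::data.table(gene_id = pairs$gene_a, log2fc = fa),
    data.table::data.table(gene_id = pairs$gene_b, log2fc = fb))
  expect_lt(abs(res$delta_coef - beta), 3 * res$delta_se)
  expect_lt(res$delta_p, 1e-6)
})

test_that("gene-set over-representation matches the hand hypergeometric", {
  universe <- paste0("g", 1:10)
  sets <- list(S = paste0("g", 1:5))
  res <- geneset_enrichment(paste0("g", 1:3), universe, sets)
  expect_equal(res$p, 10 / 120)
  # query = universe: p = 1 for every set
  res2 <- geneset_enrichment(universe, universe, sets)
  expect_equal(res2$p, 1)
  # disjoint query: fold 0, p = 1
  res3 <- geneset_enrichment(paste0("g", 6:8), universe, sets)
  expect_equal(res3$fold, 0)
  expect_equal(res3$p, 1)
})
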