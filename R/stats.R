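# The statistical battery linking promoter features to expression dynamics:
# cluster enrichment, presence t-tests, dosage/distance curves, rank-bin
# correlation, multiple regression, expression-count correlation, ortholog
# deltas and gene-set over-representation. Multiple testing is
# Benjamini-Hochberg throughout; t-tests are Welch's two-sided.

#' Repeat-feature enrichment in gene clusters
#'
#' For every (feature, cluster) pair a 2x2 table of (in cluster vs all other
#' clusters combined) x (has >= 1 vs none) is tested with a Pearson
#' chi-square without continuity correction; Fisher's exact test replaces the
#' p-value when any expected cell is below 5. BH FDR is applied over all
#' tests jointly.
#'
#' @param feat_bin Logical/0-1 matrix (genes x features) of feature presence,
#'   with rownames.
#' @param clusters Named vector gene_id -> cluster label.
#' @return `data.table`: `feature`, `cluster`, `n_with`, `n_without`,
#'   `n_with_bg`, `n_without_bg`, `frac_in`, `frac_bg`, `fold_enrichment`,
#'   `chi2`, `p`, `method`, `fdr`.
#' @export
cluster_enrichment <- function(feat_bin, clusters) {
  genes <- intersect(rownames(feat_bin), names(clusters))
  if (length(unique(clusters[genes])) < 2L) stop("need >= 2 clusters")
  fb <- feat_bin[genes, , drop = FALSE] > 0
  cl <- clusters[genes]
  res <- list()
  for (feature in colnames(fb)) {
    has <- fb[, feature]
    if (!any(has)) next  # absent everywhere: skipped
    for (cluster in sort(unique(cl))) {
      inc <- cl == cluster
      tab <- rbind(c(sum(has & inc), sum(!has & inc)),
                   c(sum(has & !inc), sum(!has & !inc)))
      tst <- test_2x2(tab)
      frac_in <- tab[1, 1] / sum(tab[1, ])
      frac_bg <- tab[2, 1] / sum(tab[2, ])
      res[[length(res) + 1L]] <- data.table::data.table(
        feature = feature, cluster = as.character(cluster),
        n_with = tab[1, 1], n_without = tab[1, 2],
        n_with_bg = tab[2, 1], n_without_bg = tab[2, 2],
        frac_in = frac_in, frac_bg = frac_bg,
        fold_enrichment = if (frac_bg > 0) frac_in / frac_bg else NA_real_,
        chi2 = tst$chi2, p = tst$p, method = tst$method)
    }
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) > 0L) out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  out[]
}

# internal: Pearson chi-square (no continuity correction), Fisher fallback
# when any expected cell < 5
test_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(chi2 = 0, p = 1, method = "degenerate"))
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(cs$expected < 5)) {
    list(chi2 = unname(cs$statistic),
         p = stats::fisher.test(tab)$p.value, method = "fisher")
  } else {
    list(chi2 = unname(cs$statistic), p = unname(cs$p.value),
         method = "chisq")
  }
}

#' Fold-change difference between feature carriers and non-carriers
#'
#' Per feature, a two-sided Welch t-test of the fold-change of genes with
#' >= 1 occurrence versus genes with none, with BH FDR across features.
#'
#' @param feat_bin Presence matrix (genes x features) with rownames.
#' @param fc Fold-change table from [fold_change()].
#' @return `data.table`: `feature`, `n_with`, `n_without`, `mean_with`,
#'   `mean_without`, `diff`, `t`, `p`, `degenerate`, `fdr`.
#' @export
presence_fc_test <- function(feat_bin, fc) {
  genes <- intersect(rownames(feat_bin), fc$gene_id)
  y <- stats::setNames(fc$log2fc, fc$gene_id)[genes]
  fb <- feat_bin[genes, , drop = FALSE] > 0
  res <- lapply(colnames(fb), function(feature) {
    a <- y[fb[, feature]]
    b <- y[!fb[, feature]]
    base <- data.table::data.table(
      feature = feature, n_with = length(a), n_without = length(b),
      mean_with = mean(a), mean_without = mean(b), diff = mean(a) - mean(b))
    if (length(a) < 2L || length(b) < 2L) {
      return(cbind(base, t = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      cbind(base, t = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      cbind(base, t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
    }
  })
  out <- data.table::rbindlist(res)
  out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  out[]
}

#' Dosage curve: fold-change by promoter copy-number category
#'
#' Genes are binned by copy count via [dosage_bin()]; per bin the mean
#' fold-change and its standard error are reported, with a Welch t-test
#' between each adjacent pair of bins and conventional star coding.
#'
#' @param counts Named integer vector gene_id -> copy count for one feature.
#' @param fc Fold-change table.
#' @param cap Top dosage category (default 5).
#' @return `data.table`: `category`, `n_genes`, `mean_log2fc`, `se`,
#'   `p_vs_prev`, `stars`.
#' @export
dosage_analysis <- function(counts, fc, cap = 5L) {
  genes <- intersect(names(counts), fc$gene_id)
  y <- stats::setNames(fc$log2fc, fc$gene_id)[genes]
  bins <- dosage_bin(counts[genes], cap = cap)
  lev <- levels(bins)
  vals <- split(unname(y), bins)
  out <- data.table::data.table(
    category = lev,
    n_genes = vapply(vals, length, integer(1)),
    mean_log2fc = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                         numeric(1)),
    se = vapply(vals, function(v) {
      if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)))
  p <- rep(NA_real_, length(lev))
  for (i in seq_along(lev)[-1]) {
    a <- vals[[lev[i]]]; b <- vals[[lev[i - 1]]]
    if (length(a) >= 2L && length(b) >= 2L) {
      p[i] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    }
  }
  out[, "p_vs_prev" := p]
  out[, "stars" := p_stars(p)]
  out[]
}

# internal star coding at p < 0.05 / 0.01 / 0.001
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Distance curve: fold-change by nearest-occurrence distance bin
#'
#' Genes are assigned by the distance of their nearest occurrence to the TSS;
#' genes with no occurrence form the reference category. Per bin the mean
#' fold-change, SE, and a Welch t-test against the reference are reported.
#'
#' @param nearest Named vector gene_id -> nearest distance in bp (NA = none).
#' @param fc Fold-change table.
#' @param edges Distance bin edges (see [distance_bins()]).
#' @return `data.table`: `category` (bins plus `"none"`), `n_genes`,
#'   `mean_log2fc`, `se`, `diff_vs_none`, `t_vs_none`, `p_vs_none`, `stars`.
#' @export
distance_analysis <- function(nearest, fc, edges = c(0, 1000, 2000, 3000, 5000, 7000, 10000)) {
  genes <- intersect(names(nearest), fc$gene_id)
  y <- stats::setNames(fc$log2fc, fc$gene_id)[genes]
  d <- nearest[genes]
  bins <- distance_bins(d, edges)
  ref <- unname(y[is.na(bins)])
  lev <- levels(bins)
  res <- lapply(lev, function(b) {
    v <- unname(y[!is.na(bins) & bins == b])
    tt <- if (length(v) >= 2L && length(ref) >= 2L) {
      tryCatch(stats::t.test(v, ref), error = function(e) NULL)
    } else NULL
    data.table::data.table(
      category = b, n_genes = length(v),
      mean_log2fc = if (length(v)) mean(v) else NA_real_,
      se = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      diff_vs_none = if (length(v)) mean(v) - mean(ref) else NA_real_,
      t_vs_none = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
      p_vs_none = if (!is.null(tt)) tt$p.value else NA_real_)
  })
  out <- data.table::rbindlist(res)
  out <- rbind(out, data.table::data.table(
    category = "none", n_genes = length(ref), mean_log2fc = mean(ref),
    se = stats::sd(ref) / sqrt(length(ref)), diff_vs_none = 0,
    t_vs_none = NA_real_, p_vs_none = NA_real_))
  out[, "stars" := p_stars(out$p_vs_none)]
  out[]
}

#' Correlation of per-bin mean fold-change with feature prevalence
#'
#' One point per rank bin: the bin's mean log2 fold-change against the
#' fraction of its genes carrying the feature; Pearson correlation with a
#' two-sided p from the t transform on `n_bins - 2` df.
#'
#' @param bins Rank-bin table from [rank_bins()].
#' @param feat_bin Named presence vector gene_id -> 0/1 for one feature.
#' @return List with `pcc`, `p`, `n_bins`, `per_bin` (`data.table`), and
#'   `degenerate` (TRUE when the correlation is undefined).
#' @export
bin_correlation <- function(bins, feat_bin) {
  b <- data.table::as.data.table(bins)
  b[, "has" := feat_bin[b$gene_id] > 0]
  per_bin <- b[, list(mean_log2fc = mean(log2fc), frac_with = mean(has),
                      n = .N), by = "bin"]
  data.table::setorder(per_bin, bin)
  if (nrow(per_bin) < 3L) stop("need >= 3 bins")
  if (stats::sd(per_bin$frac_with) == 0 || stats::sd(per_bin$mean_log2fc) == 0) {
    return(list(pcc = NA_real_, p = NA_real_, n_bins = nrow(per_bin),
                per_bin = per_bin, degenerate = TRUE))
  }
  ct <- stats::cor.test(per_bin$mean_log2fc, per_bin$frac_with,
                        method = "pearson")
  list(pcc = unname(ct$estimate), p = ct$p.value, n_bins = nrow(per_bin),
       per_bin = per_bin, degenerate = FALSE)
}

#' Multiple regression of fold-change on promoter features
#'
#' Ordinary least squares of per-gene fold-change on feature columns
#' (typically per-type repeat counts split by orientation, plus CpG and TFBS
#' counts), with two-sided t p-values and BH FDR. Zero-variance columns are
#' dropped with a note; perfectly collinear columns are detected via aliased
#' coefficients and dropped deterministically (columns are processed in
#' lexicographic order, the later duplicate is removed).
#'
#' @param fc Fold-change table.
#' @param X Numeric feature matrix (genes x features) with dimnames.
#' @param min_genes Features present (nonzero) in fewer genes are excluded
#'   (default 20).
#' @return `data.table` of per-feature `estimate`, `se`, `t`, `p`, `fdr`,
#'   with attributes `n`, `r_squared`, `dropped` and `intercept`.
#' @export
multiple_regression <- function(fc, X, min_genes = 20L) {
  genes <- intersect(fc$gene_id, rownames(X))
  y <- stats::setNames(fc$log2fc, fc$gene_id)[genes]
  X <- X[genes, order(colnames(X)), drop = FALSE]
  dropped <- character(0)
  rare <- colSums(X != 0) < min_genes
  if (any(rare)) {
    dropped <- c(dropped, colnames(X)[rare])
    X <- X[, !rare, drop = FALSE]
  }
  zv <- apply(X, 2, stats::sd) == 0
  if (any(zv)) {
    dropped <- c(dropped, colnames(X)[zv])
    X <- X[, !zv, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no usable features left")
  fit <- stats::lm(y ~ X)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    bad <- sub("^X", "", names(stats::coef(fit))[aliased])
    warning("dropping collinear column(s): ", paste(bad, collapse = ", "))
    dropped <- c(dropped, bad)
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    fit <- stats::lm(y ~ X)
  }
  if (length(y) <= ncol(X) + 1L) stop("n <= p after drops")
  sm <- summary(fit)
  co <- sm$coefficients
  feat_rows <- rownames(co) != "(Intercept)"
  out <- data.table::data.table(
    feature = sub("^X", "", rownames(co)[feat_rows]),
    estimate = co[feat_rows, 1], se = co[feat_rows, 2],
    t = co[feat_rows, 3], p = co[feat_rows, 4])
  out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  data.table::setattr(out, "n", length(y))
  data.table::setattr(out, "r_squared", sm$r.squared)
  data.table::setattr(out, "dropped", dropped)
  data.table::setattr(out, "intercept", unname(co["(Intercept)", 1]))
  out[]
}

#' Per-sample correlation of expression with promoter copy counts
#'
#' Pearson correlation of `log2(expression + pc)` with per-gene copy counts,
#' per sample, optionally as a partial correlation controlling a covariate
#' (residual-on-residual).
#'
#' @param expr An `expr_set`.
#' @param counts Named vector gene_id -> copy count.
#' @param pseudocount Added before log (default 1).
#' @param control Optional named covariate vector (e.g. CpG-island counts) to
#'   partial out.
#' @return `data.table`: `sample`, `stage`, `pcc`, `p`, `n`.
#' @export
expression_count_correlation <- function(expr, counts, pseudocount = 1,
                                         control = NULL) {
  genes <- intersect(rownames(expr$mat), names(counts))
  x <- counts[genes]
  res <- lapply(expr$design$sample, function(smp) {
    v <- log2(expr$mat[genes, smp] + pseudocount)
    if (is.null(control)) {
      ct <- stats::cor.test(v, x)
      pcc <- unname(ct$estimate); p <- ct$p.value
    } else {
      z <- control[genes]
      rv <- stats::resid(stats::lm(v ~ z))
      rx <- stats::resid(stats::lm(x ~ z))
      if (stats::sd(rx) <= 1e-8 * stats::sd(x) ||
          stats::sd(rv) <= 1e-8 * stats::sd(v)) {
        pcc <- 0; p <- NA_real_
      } else {
        ct <- stats::cor.test(rv, rx)
        pcc <- unname(ct$estimate); p <- ct$p.value
      }
    }
    data.table::data.table(
      sample = smp,
      stage = expr$design$stage[expr$design$sample == smp],
      pcc = pcc, p = p, n = length(genes))
  })
  data.table::rbindlist(res)
}

#' Cross-species ortholog association of promoter counts and fold-changes
#'
#' Across ortholog pairs: the Pearson correlation of promoter copy counts
#' between the two species, and a regression of the fold-change difference on
#' the count difference.
#'
#' @param pairs `data.table` with columns `gene_a`, `gene_b`.
#' @param counts_a,counts_b Named count vectors for species A and B.
#' @param fc_a,fc_b Fold-change tables for species A and B.
#' @return List: `n_pairs`, `count_pcc`, `count_p`, `delta_coef`, `delta_se`,
#'   `delta_p`, `delta_r_squared`.
#' @export
ortholog_delta_association <- function(pairs, counts_a, counts_b, fc_a, fc_b) {
  pr <- data.table::as.data.table(pairs)
  pr <- pr[pr$gene_a %in% names(counts_a) & pr$gene_b %in% names(counts_b)]
  if (nrow(pr) == 0L) stop("empty ortholog pair list after matching")
  ca <- counts_a[pr$gene_a]; cb <- counts_b[pr$gene_b]
  ct <- stats::cor.test(ca, cb)
  ya <- stats::setNames(fc_a$log2fc, fc_a$gene_id)[pr$gene_a]
  yb <- stats::setNames(fc_b$log2fc, fc_b$gene_id)[pr$gene_b]
  dfc <- ya - yb
  dcount <- ca - cb
  keep <- is.finite(dfc) & is.finite(dcount)
  if (stats::sd(dcount[keep]) == 0) {
    # identical counts: the delta regression is undefined
    return(list(n_pairs = nrow(pr), count_pcc = unname(ct$estimate),
                count_p = ct$p.value, delta_coef = NA_real_,
                delta_se = NA_real_, delta_p = NA_real_,
                delta_r_squared = NA_real_))
  }
  fit <- summary(stats::lm(dfc[keep] ~ dcount[keep]))
  list(n_pairs = nrow(pr), count_pcc = unname(ct$estimate),
       count_p = ct$p.value,
       delta_coef = fit$coefficients[2, 1], delta_se = fit$coefficients[2, 2],
       delta_p = fit$coefficients[2, 4], delta_r_squared = fit$r.squared)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided over-representation p-value `P(X >= k)` per set, with fold
#' enrichment and BH FDR across sets.
#'
#' @param query Character vector of query gene ids (e.g. genes with multiple
#'   promoter copies of a repeat).
#' @param universe Character vector of background gene ids.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @return `data.table`: `set`, `n_set`, `n_query`, `n_overlap`, `fold`, `p`,
#'   `fdr`.
#' @export
geneset_enrichment <- function(query, universe, collections) {
  query <- intersect(query, universe)
  nq <- length(query); nu <- length(universe)
  res <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], universe)
    m <- length(set)
    k <- length(intersect(query, set))
    p <- if (m == 0L || nq == 0L) 1 else
      stats::phyper(k - 1, m, nu - m, nq, lower.tail = FALSE)
    fold <- if (m == 0L || nq == 0L) NA_real_ else (k / nq) / (m / nu)
    data.table::data.table(set = nm, n_set = m, n_query = nq, n_overlap = k,
                           fold = fold, p = p)
  })
  out <- data.table::rbindlist(res)
  out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  out[]
}
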