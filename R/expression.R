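# Expression filtering, stage fold-changes, and the clustering steps that
# define gene groups (temporal clusters, k-means tissue clusters, blastocyst
# sample subtypes, fold-change rank bins).

#' Filter genes by expression level and variability
#'
#' Genes whose maximum over all samples is below `min_level` are removed; the
#' survivors are ranked by standard deviation across samples (descending) and
#' the top `top_n` kept. If fewer than `top_n` survive, all are kept.
#'
#' @param expr An `expr_set`.
#' @param min_level Minimum expression any sample must reach (default 5).
#' @param top_n Number of most-variable genes to keep (default 12000).
#' @return Character vector of gene ids, in descending-SD order.
#' @export
filter_genes <- function(expr, min_level = 5, top_n = 12000L) {
  mx <- apply(expr$mat, 1, max)
  keep <- expr$mat[mx >= min_level, , drop = FALSE]
  sds <- apply(keep, 1, stats::sd)
  ord <- order(-sds, rownames(keep))
  head(rownames(keep)[ord], top_n)
}

#' Log2 fold-change between two stages
#'
#' `log2((mean_to + pc) / (mean_from + pc))` per gene, means taken over the
#' samples of each stage on the raw scale.
#'
#' @param expr An `expr_set`.
#' @param from_stage,to_stage Stage labels present in the design.
#' @param pseudocount Stabilising pseudocount (default 1 expression unit).
#' @param genes Optional subset of gene ids.
#' @return `data.table` with `gene_id`, `log2fc`; attributes `stage_pair` and
#'   `pseudocount`.
#' @export
fold_change <- function(expr, from_stage, to_stage, pseudocount = 1,
                        genes = NULL) {
  if (!all(c(from_stage, to_stage) %in% expr$stage_order)) {
    stop("unknown stage: ",
         paste(setdiff(c(from_stage, to_stage), expr$stage_order), collapse = ", "))
  }
  mat <- expr$mat
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  from_cols <- expr$design$sample[expr$design$stage == from_stage]
  to_cols <- expr$design$sample[expr$design$stage == to_stage]
  fc <- log2((rowMeans(mat[, to_cols, drop = FALSE]) + pseudocount) /
             (rowMeans(mat[, from_cols, drop = FALSE]) + pseudocount))
  out <- data.table::data.table(gene_id = rownames(mat), log2fc = fc)
  data.table::setattr(out, "stage_pair", c(from = from_stage, to = to_stage))
  data.table::setattr(out, "pseudocount", pseudocount)
  out
}

# internal: per-row standardization (mean 0, SD 1)
row_standardize <- function(mat) {
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  (mat - m) / s
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with `1 - Pearson correlation` as the distance
#' and average linkage, cut into exactly `k` groups. Rows are standardised
#' (mean 0, SD 1) by default, and canonically ordered by name first so the
#' result is invariant to input row order; zero-variance rows are dropped
#' with a warning.
#'
#' @param mat Numeric matrix (genes x samples) with rownames.
#' @param k Number of clusters.
#' @param row_standardize Standardise rows before clustering (default TRUE).
#' @return List with `labels` (named integer vector, cluster ids 1..k) and
#'   `tree` (the `hclust` object).
#' @export
hierarchical_cluster <- function(mat, k, row_standardize = TRUE) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  v <- apply(mat, 1, stats::sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance row(s)")
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (k > nrow(mat)) stop("k exceeds the number of rows (", nrow(mat), ")")
  x <- if (row_standardize) row_standardize(mat) else mat
  d <- stats::as.dist(1 - stats::cor(t(x)))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' K-means clustering of expression profiles
#'
#' Lloyd's algorithm on row-standardised profiles, best of `n_init` seeded
#' restarts by within-cluster sum of squares.
#'
#' @param mat Numeric matrix (genes x samples) with rownames.
#' @param k Number of clusters (default 25).
#' @param seed RNG seed (recorded in the result).
#' @param n_init Number of random restarts (default 10).
#' @return List with `labels` (named integer vector), `tot_withinss`, `seed`.
#' @export
kmeans_cluster <- function(mat, k = 25L, seed = 1L, n_init = 10L) {
  if (k > nrow(mat)) stop("k exceeds the number of rows (", nrow(mat), ")")
  x <- row_standardize(mat)
  x <- x[apply(is.finite(x), 1, all), , drop = FALSE]
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 200L,
                  algorithm = "Lloyd"))
  list(labels = stats::setNames(km$cluster, rownames(x)),
       tot_withinss = km$tot.withinss, seed = seed)
}

#' Contiguous rank bins of genes sorted by fold-change
#'
#' Genes are sorted by fold-change descending (ties by `gene_id`) and split
#' into consecutive bins of `group_size`. A trailing remainder bin is kept
#' (and flagged) if it holds at least `group_size / 2` genes, otherwise
#' dropped with a warning.
#'
#' @param fc A fold-change table from [fold_change()].
#' @param group_size Genes per bin (default 500).
#' @return `data.table` with `gene_id`, `log2fc`, `bin` (1 = highest
#'   fold-change); attribute `remainder_kept`.
#' @export
rank_bins <- function(fc, group_size = 500L) {
  stopifnot(group_size >= 2L)
  x <- data.table::as.data.table(fc)[order(-log2fc, gene_id)]
  n <- nrow(x)
  n_full <- n %/% group_size
  rem <- n - n_full * group_size
  x[, "bin" := rep(seq_len(n_full + 1L),
                   c(rep(group_size, n_full), rem))[seq_len(n)]]
  remainder_kept <- FALSE
  if (rem > 0L) {
    if (rem >= group_size / 2) {
      remainder_kept <- TRUE
    } else {
      warning("dropping remainder bin of ", rem, " genes")
      x <- x[x$bin <= n_full]
    }
  }
  data.table::setattr(x, "remainder_kept", remainder_kept)
  x[]
}

#' Split samples of one stage into subtypes by hierarchical clustering
#'
#' Hierarchical clustering (1 - Pearson, average linkage) applied to samples
#' (columns) rather than genes; clusters are labelled 1..k by decreasing
#' size.
#'
#' @param expr An `expr_set` restricted to the samples to split (e.g. the
#'   blastocyst samples).
#' @param k Number of subtypes (default 3).
#' @return Named integer vector sample -> subtype label.
#' @export
split_sample_types <- function(expr, k = 3L) {
  if (ncol(expr$mat) < k) stop("fewer than ", k, " samples")
  res <- hierarchical_cluster(t(expr$mat), k = k, row_standardize = FALSE)
  labels <- res$labels
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- relabel[as.character(labels)]
  names(out) <- names(labels)
  out
}
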