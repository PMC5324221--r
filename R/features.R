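# Promoters x repeat annotation -> the per-gene feature table every
# downstream statistic consumes. Counting unit is the repeat record
# (fragment); a repeat overlapping two genes' promoters counts for both.

#' Build the per-gene promoter feature table
#'
#' For every promoter window, counts overlapping repeat records (>= 1 shared
#' base) at the requested level, split by orientation relative to the gene
#' (`same`/`opposite`, plus their sum `any`), computes per-family coverage of
#' the window by merged repeat intervals, and the nearest distance to the TSS
#' per repeat name. Optional CpG-island and TFBS interval sets contribute
#' orientation-pooled counts/coverage (unstranded intervals count on both
#' strands), and an optional genome adds a CpG-dinucleotide count of the
#' window sequence.
#'
#' @param promoters Promoter table from [make_promoters()].
#' @param repeats Repeat table from [read_repeatmasker()] (or the generator).
#' @param level Feature level: `"name"`, `"family"` or `"klass"`.
#' @param cpg_intervals Optional `data.table` of CpG-island intervals (BED).
#' @param tfbs_intervals Optional `data.table` of TF-binding intervals with a
#'   `name` column carrying the TF.
#' @param genome Optional `DNAStringSet` for CpG dinucleotide counts.
#' @param coverage_families Character vector of families for which coverage is
#'   computed (default: all families present).
#' @param distance_names Repeat names for which `nearest.<name>` distance
#'   columns are emitted (default: none; distance analyses usually use a wider
#'   window than counting).
#' @param distance_orientation Orientation filter for the nearest-distance
#'   columns: `"any"` (default, pooled), `"same"` or `"opposite"` relative to
#'   the gene strand.
#' @return `data.table` keyed by `gene_id`, one row per promoter, with columns
#'   `count.<level>.<feature>.<same|opposite|any>`, `coverage.<family>`,
#'   `nearest.<name>`, `cpg_island_count`, `cpg_island_coverage`,
#'   `tfbs_count.<tf>`, `cpg_dinucleotide_count` as applicable. Genes with no
#'   overlap get zero counts (NA for distances).
#' @export
build_feature_table <- function(promoters, repeats, level = c("name", "family", "klass"),
                                cpg_intervals = NULL, tfbs_intervals = NULL,
                                genome = NULL, coverage_families = NULL,
                                distance_names = character(0),
                                distance_orientation = c("any", "same", "opposite")) {
  distance_orientation <- match.arg(distance_orientation)
  level <- match.arg(level)
  prom <- data.table::as.data.table(promoters)
  # rows stay in promoter order throughout; all per-window vectors below are
  # positional
  out <- data.table::data.table(gene_id = prom$gene_id)

  missing_chr <- setdiff(unique(prom$chrom), unique(repeats$chrom))
  if (length(missing_chr) > 0L) {
    warning("chromosome(s) in promoters absent from repeat annotation: ",
            paste(missing_chr, collapse = ", "), " (zero counts)")
  }

  hits <- overlap_pairs(prom, repeats)
  if (nrow(hits) > 0L) {
    hits[, "feature" := repeats[[level]][hits$rep_idx]]
    hits[, "orientation" := ifelse(repeats$strand[hits$rep_idx] ==
                                     prom$strand[hits$prom_idx],
                                   "same", "opposite")]
  }

  feats <- sort(unique(repeats[[level]]))
  for (orient in c("same", "opposite", "any")) {
    cnt <- count_matrix(hits, prom, feats,
                        if (orient == "any") NULL else orient)
    colnames(cnt) <- paste("count", level, feats, orient, sep = ".")
    out <- cbind(out, data.table::as.data.table(cnt))
  }

  if (is.null(coverage_families)) coverage_families <- sort(unique(repeats$family))
  for (fam in coverage_families) {
    out[, paste0("coverage.", fam) :=
          window_coverage(prom, repeats[repeats$family == fam])]
  }

  for (nm in distance_names) {
    sel <- repeats$name == nm
    if (distance_orientation != "any") {
      # orientation filter needs the gene strand, so restrict per promoter
      # strand: do it by splitting promoters by strand
      res <- rep(NA_integer_, nrow(prom))
      for (gs in c("+", "-")) {
        pi <- which(prom$strand == gs)
        if (length(pi) == 0L) next
        want <- if (distance_orientation == "same") gs else
          setdiff(c("+", "-"), gs)
        res[pi] <- nearest_tss_distance(prom[pi],
                                        repeats[which(sel & repeats$strand == want)])
      }
      out[, paste0("nearest.", nm) := res]
    } else {
      out[, paste0("nearest.", nm) := nearest_tss_distance(prom, repeats[which(sel)])]
    }
  }

  if (!is.null(cpg_intervals)) {
    ch <- overlap_pairs(prom, cpg_intervals)
    n <- tabulate(ch$prom_idx, nbins = nrow(prom))
    out[, "cpg_island_count" := n]
    out[, "cpg_island_coverage" := window_coverage(prom, cpg_intervals)]
  }

  if (!is.null(tfbs_intervals)) {
    th <- overlap_pairs(prom, tfbs_intervals)
    tfs <- sort(unique(tfbs_intervals$name))
    if (nrow(th) > 0L) th[, "feature" := tfbs_intervals$name[th$rep_idx]]
    cnt <- count_matrix(th, prom, tfs, NULL)
    colnames(cnt) <- paste0("tfbs_count.", tfs)
    out <- cbind(out, data.table::as.data.table(cnt))
  }

  if (!is.null(genome)) {
    out[, "cpg_dinucleotide_count" := cpg_dinucleotides(prom, genome)]
  }

  out[]
}

# internal: all (promoter, interval) overlap pairs as a data.table of indices
overlap_pairs <- function(prom, intervals) {
  if (nrow(intervals) == 0L) {
    return(data.table::data.table(prom_idx = integer(), rep_idx = integer()))
  }
  ov <- GenomicRanges::findOverlaps(as_granges0(prom, use_strand = FALSE),
                                    as_granges0(intervals, use_strand = FALSE),
                                    ignore.strand = TRUE)
  data.table::data.table(prom_idx = S4Vectors::queryHits(ov),
                         rep_idx = S4Vectors::subjectHits(ov))
}

# internal: promoters x features count matrix, optionally orientation-filtered
count_matrix <- function(hits, prom, feats, orientation) {
  cnt <- matrix(0L, nrow = nrow(prom), ncol = length(feats),
                dimnames = list(NULL, feats))
  if (nrow(hits) > 0L && length(feats) > 0L) {
    keep <- if (is.null(orientation)) rep(TRUE, nrow(hits)) else
      hits$orientation == orientation
    h <- hits[which(keep)]
    if (nrow(h) > 0L) {
      tab <- h[, list(n = .N), by = c("prom_idx", "feature")]
      cnt[cbind(tab$prom_idx, match(tab$feature, feats))] <- tab$n
    }
  }
  cnt
}

# internal: fraction of each window covered by the union of the intervals
window_coverage <- function(prom, intervals) {
  if (nrow(intervals) == 0L) return(rep(0, nrow(prom)))
  h <- overlap_pairs(prom, intervals)
  cov <- rep(0, nrow(prom))
  if (nrow(h) == 0L) return(cov)
  h[, "s" := pmax(intervals$start[h$rep_idx], prom$start[h$prom_idx])]
  h[, "e" := pmin(intervals$end[h$rep_idx], prom$end[h$prom_idx])]
  data.table::setorder(h, prom_idx, s, e)
  merged <- h[, {
    # union length of clipped, sorted intervals
    hi <- cummax(e)
    new_block <- c(TRUE, s[-1] > hi[-.N])
    block <- cumsum(new_block)
    list(len = sum(vapply(split(seq_len(.N), block), function(i) {
      max(e[i]) - min(s[i])
    }, numeric(1))))
  }, by = "prom_idx"]
  cov[merged$prom_idx] <- merged$len /
    (prom$end[merged$prom_idx] - prom$start[merged$prom_idx])
  cov
}

# internal: per promoter, min |distance to TSS| over overlapping records
nearest_tss_distance <- function(prom, intervals) {
  res <- rep(NA_integer_, nrow(prom))
  if (nrow(intervals) == 0L) return(res)
  h <- overlap_pairs(prom, intervals)
  if (nrow(h) == 0L) return(res)
  h[, "d" := abs(distance_to_tss(intervals$start[h$rep_idx],
                                 intervals$end[h$rep_idx],
                                 prom$tss[h$prom_idx],
                                 prom$strand[h$prom_idx]))]
  nd <- h[, list(d = min(d)), by = "prom_idx"]
  res[nd$prom_idx] <- nd$d
  res
}

# internal: "CG" occurrences on the + strand of each window (strand-symmetric)
cpg_dinucleotides <- function(prom, genome) {
  vapply(seq_len(nrow(prom)), function(i) {
    chr <- genome[[prom$chrom[i]]]
    s <- Biostrings::subseq(chr, prom$start[i] + 1L, prom$end[i])
    Biostrings::countPattern("CG", s)
  }, integer(1))
}

#' Bin a copy count into dosage categories
#'
#' Counts of `cap` or more collapse into a single top category, mirroring
#' dosage analyses that pool genes with five or more elements.
#'
#' @param count Nonnegative integer vector.
#' @param cap Top category threshold (default 5).
#' @return Factor with levels `"0", "1", ..., ">=cap"`.
#' @export
dosage_bin <- function(count, cap = 5L) {
  if (any(count < 0L, na.rm = TRUE)) stop("negative count")
  levels <- c(as.character(seq(0L, cap - 1L)), paste0(">=", cap))
  lab <- ifelse(count >= cap, paste0(">=", cap), as.character(count))
  factor(lab, levels = levels)
}

#' Bin nearest-TSS distances into right-open intervals
#'
#' Bins are `[e_i, e_{i+1})`; a distance of 0 (repeat covers the TSS) falls in
#' the first bin; distances at or beyond the last edge (and NA) are NA.
#'
#' @param distance Nonnegative distances in bp (NA = no occurrence).
#' @param edges Strictly increasing bin edges in bp, starting at 0.
#' @return Factor of bin labels `"[e_i,e_{i+1})"`.
#' @export
distance_bins <- function(distance, edges) {
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  labels <- sprintf("[%d,%d)", edges[-length(edges)], edges[-1])
  idx <- findInterval(distance, edges, rightmost.closed = FALSE)
  idx[idx == length(edges)] <- NA  # at/beyond last edge
  idx[idx == 0L] <- NA             # below first edge
  factor(labels[idx], levels = labels)
}
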