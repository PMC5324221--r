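# TSS selection and strand-aware promoter windows. Windows are defined in
# gene orientation: `upstream` bases 5' of the TSS and `downstream` bases
# starting at the TSS, mirrored exactly on the minus strand so that the base
# at the TSS is included iff downstream >= 1.

#' Select one TSS per gene
#'
#' The TSS of the highest-expressed transcript isoform (mean across all
#' samples) is chosen per gene. Ties are broken by lexicographically smallest
#' `transcript_id`. Genes with no expressed transcript — or when no
#' transcript-level expression is supplied — fall back to the outermost
#' (5'-most in gene orientation) TSS.
#'
#' @param transcripts Transcript table from [read_gtf()].
#' @param expr Optional `expr_set` at transcript level (rownames are
#'   transcript ids).
#' @return `data.table` with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `transcript_id` (the chosen isoform), `tss_source`
#'   (`"expression"` or `"outermost"`).
#' @export
select_tss <- function(transcripts, expr = NULL) {
  tx <- data.table::copy(transcripts)
  mean_expr <- rep(NA_real_, nrow(tx))
  if (!is.null(expr)) {
    hit <- match(tx$transcript_id, rownames(expr$mat))
    mean_expr[!is.na(hit)] <- rowMeans(expr$mat)[hit[!is.na(hit)]]
  }
  tx[, "mean_expr" := mean_expr]
  data.table::setorder(tx, gene_id, transcript_id)
  out <- tx[, {
    expressed <- !is.na(mean_expr) & mean_expr > 0
    if (any(expressed)) {
      i <- which(expressed)[which.max(mean_expr[expressed])]
      src <- "expression"
    } else {
      # outermost TSS: 5'-most in gene orientation
      i <- if (strand[1] == "+") which.min(tss) else which.max(tss)
      src <- "outermost"
    }
    list(chrom = chrom[1], strand = strand[1], tss = tss[i],
         transcript_id = transcript_id[i], tss_source = src)
  }, by = gene_id]
  data.table::setorder(out, chrom, tss, gene_id)
  out[]
}

#' Build strand-aware promoter windows around TSSs
#'
#' On the `+` strand the window is `[tss - upstream, tss + downstream)`; on
#' the `-` strand it is the exact mirror, `[tss - downstream + 1,
#' tss + upstream + 1)`. Windows are clipped to `[0, contig_length)`; windows
#' that clip to zero length are dropped with a warning.
#'
#' @param tss_map `data.table` with `gene_id`, `chrom`, `strand`, `tss` (from
#'   [select_tss()]).
#' @param upstream,downstream Window extent in bp (each >= 0).
#' @param contig_lengths Named integer vector of contig lengths.
#' @return `data.table`: `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `clipped` (logical).
#' @export
make_promoters <- function(tss_map, upstream = 2000L, downstream = 0L,
                           contig_lengths) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  p <- data.table::as.data.table(tss_map)[, c("gene_id", "chrom", "strand", "tss"),
                                          with = FALSE]
  len <- contig_lengths[p$chrom]
  if (anyNA(len)) {
    stop("contig length missing for chromosome(s): ",
         paste(unique(p$chrom[is.na(len)]), collapse = ", "))
  }
  if (any(p$tss < 0L | p$tss >= len)) {
    stop("TSS outside contig for gene(s): ",
         paste(p$gene_id[p$tss < 0L | p$tss >= len], collapse = ", "))
  }
  plus <- p$strand == "+"
  raw_start <- ifelse(plus, p$tss - upstream, p$tss - downstream + 1L)
  raw_end <- ifelse(plus, p$tss + downstream, p$tss + upstream + 1L)
  p[, "start" := pmax(raw_start, 0L)]
  p[, "end" := pmin(raw_end, as.integer(len))]
  p[, "clipped" := p$start != raw_start | p$end != raw_end]
  empty <- p$start >= p$end
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty promoter window(s)")
    p <- p[!empty]
  }
  data.table::setattr(p, "window_spec", c(upstream = upstream,
                                          downstream = downstream))
  data.table::setorder(p, chrom, start, gene_id)
  p[]
}

#' Build a searchable interval index
#'
#' @param dt Interval `data.table` (`chrom`, `start`, `end`, 0-based
#'   half-open); rows become payload indices.
#' @return An `interval_index` object.
#' @export
interval_index <- function(dt) {
  structure(list(gr = as_granges0(dt, use_strand = FALSE), payload = dt),
            class = "interval_index")
}

#' Query an interval index
#'
#' An overlap is any shared base (>= 1 bp) between half-open intervals.
#'
#' @param index An [interval_index()].
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Integer vector of payload row indices overlapping the query.
#' @export
query_index <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, index$gr,
                                                     ignore.strand = TRUE))
}

#' Signed distance from a repeat to a TSS in gene orientation
#'
#' The minimum over the repeat interval of the signed distance from the TSS,
#' measured against gene orientation: upstream positive, downstream negative,
#' 0 if the repeat covers the TSS.
#'
#' @param start,end Repeat interval (0-based half-open), vectorised.
#' @param tss TSS position(s).
#' @param gene_strand `"+"` or `"-"`, vectorised.
#' @return Integer vector of signed distances in bp.
#' @export
distance_to_tss <- function(start, end, tss, gene_strand) {
  covers <- start <= tss & tss < end
  left <- end <= tss     # repeat entirely left of tss
  d <- integer(length(start))
  # distance to the nearest repeat base
  d[left] <- tss[left] - (end[left] - 1L)
  d[!left & !covers] <- tss[!left & !covers] - start[!left & !covers]  # negative
  d[covers] <- 0L
  ifelse(gene_strand == "+", d, -d) * 1L
}
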