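# Genome-wide repeat statistics: per-type copy-number distribution fit,
# inter-repeat distances, gene-region enrichment and strand preference near
# genes.

#' Lognormal fit of per-type repeat copy numbers
#'
#' Copy counts per repeat name, fitted by maximum likelihood on the natural
#' log scale (`mu` = mean of log counts, `sigma` = population SD). Goodness
#' of fit is a Kolmogorov-Smirnov test against the fitted lognormal; because
#' the parameters are estimated from the same data the p-value is
#' approximate (and flagged so).
#'
#' @param repeats Repeat table (needs a `name` column), or a named vector of
#'   counts.
#' @return List: `mu`, `sigma`, `n_types`, `ks_stat`, `ks_p`,
#'   `ks_p_approximate` (TRUE), `counts` (named per-type copy numbers).
#' @export
copy_number_fit <- function(repeats) {
  counts <- if (is.numeric(repeats)) repeats else table(repeats$name)
  counts <- as.numeric(counts[counts > 0])
  lx <- log(counts)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  ks <- if (sigma > 0) {
    suppressWarnings(stats::ks.test(counts, stats::plnorm,
                                    meanlog = mu, sdlog = sigma))
  } else NULL
  list(mu = mu, sigma = sigma, n_types = length(counts),
       ks_stat = if (!is.null(ks)) unname(ks$statistic) else NA_real_,
       ks_p = if (!is.null(ks)) ks$p.value else NA_real_,
       ks_p_approximate = TRUE,
       counts = counts)
}

#' Distances between consecutive same-name repeats
#'
#' Distances between consecutive repeat starts per chromosome for one repeat
#' name, with a histogram on logarithmic bins and a log-log slope estimate
#' (no distributional fit is asserted).
#'
#' @param repeats Repeat table.
#' @param name Repeat name to profile.
#' @param n_bins Number of logarithmic histogram bins (default 20).
#' @return List: `distances`, `histogram` (`data.table` of bin
#'   lower/upper/count), `loglog_slope` (NA when fewer than 3 non-empty
#'   bins).
#' @export
inter_repeat_distances <- function(repeats, name, n_bins = 20L) {
  sel <- which(repeats$name == name)
  r <- data.table::as.data.table(repeats)[sel]
  data.table::setorder(r, chrom, start)
  d <- unlist(lapply(split(r$start, r$chrom), diff), use.names = FALSE)
  d <- d[d > 0]
  if (length(d) == 0L) {
    return(list(distances = integer(0), histogram = data.table::data.table(),
                loglog_slope = NA_real_))
  }
  edges <- exp(seq(log(min(d)), log(max(d) + 1), length.out = n_bins + 1L))
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  hist <- data.table::data.table(
    lower = edges[-length(edges)], upper = edges[-1],
    count = tabulate(idx, nbins = n_bins))
  nz <- hist$count > 0
  slope <- if (sum(nz) >= 3L) {
    mid <- sqrt(hist$lower * hist$upper)
    dens <- hist$count / (hist$upper - hist$lower)
    unname(stats::coef(stats::lm(log(dens[nz]) ~ log(mid[nz])))[2])
  } else NA_real_
  list(distances = d, histogram = hist, loglog_slope = slope)
}

#' Classify genomic positions into gene-relative regions
#'
#' Precedence: promoter > exon > intron > downstream > intergenic. A repeat
#' is assigned by its midpoint.
#'
#' @param transcripts Transcript table from [read_gtf()].
#' @param tss_map TSS table from [select_tss()].
#' @param contig_lengths Named contig lengths.
#' @param promoter_upstream,promoter_downstream Promoter window spec
#'   (default 2000, 0).
#' @param downstream_bp Extent of the downstream region 3' of the gene end
#'   (default 2000).
#' @return A `region_model` list with per-region interval `data.table`s
#'   (`promoter`, `exon`, `intron`, `downstream`), `contig_lengths` and
#'   `region_lengths` (effective, precedence-resolved bp per region class).
#' @export
region_model <- function(transcripts, tss_map, contig_lengths,
                         promoter_upstream = 2000L, promoter_downstream = 0L,
                         downstream_bp = 2000L) {
  prom <- make_promoters(tss_map, promoter_upstream, promoter_downstream,
                         contig_lengths)
  tx <- data.table::as.data.table(transcripts)
  exon <- tx[, list(start = unlist(exon_starts), end = unlist(exon_ends)),
             by = c("chrom", "strand", "gene_id")]
  gene_span <- tx[, list(start = min(start), end = max(end)),
                  by = c("chrom", "strand", "gene_id")]
  down <- data.table::copy(gene_span)
  plus <- down$strand == "+"
  ds <- ifelse(plus, down$end, pmax(down$start - downstream_bp, 0L))
  de <- ifelse(plus, pmin(down$end + downstream_bp, contig_lengths[down$chrom]),
               down$start)
  down[, "start" := as.integer(ds)]
  down[, "end" := as.integer(de)]
  down <- down[down$start < down$end]
  model <- list(promoter = prom[, c("chrom", "start", "end", "strand", "gene_id"),
                                with = FALSE],
                exon = exon,
                intron = gene_span,  # intron = gene span minus exons, via precedence
                downstream = down,
                contig_lengths = contig_lengths)
  model$region_lengths <- region_lengths(model)
  structure(model, class = "region_model")
}

# internal: classify positions (0-based) on a chromosome by precedence
classify_positions <- function(model, chrom, pos) {
  inside <- function(dt) {
    d <- dt[dt$chrom == chrom]
    if (nrow(d) == 0L) return(rep(FALSE, length(pos)))
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), ir)
  }
  in_prom <- inside(model$promoter)
  in_exon <- inside(model$exon)
  in_gene <- inside(model$intron)  # gene span
  in_down <- inside(model$downstream)
  out <- rep("intergenic", length(pos))
  out[in_down] <- "downstream"
  out[in_gene] <- "intron"
  out[in_exon] <- "exon"
  out[in_prom] <- "promoter"
  out
}

# internal: effective per-region lengths under the precedence order
region_lengths <- function(model) {
  total <- sum(as.numeric(model$contig_lengths))
  red <- function(dt) {
    if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(as_granges0(dt, use_strand = FALSE),
                          ignore.strand = TRUE)
  }
  prom <- red(model$promoter)
  exon <- red(model$exon)
  gene <- red(model$intron)
  down <- red(model$downstream)
  w <- function(g) if (length(g) == 0L) 0 else sum(as.numeric(GenomicRanges::width(g)))
  sd_ <- GenomicRanges::setdiff
  l_prom <- w(prom)
  l_exon <- w(sd_(exon, prom))
  l_intron <- w(sd_(sd_(gene, exon), prom))
  l_down <- w(sd_(sd_(sd_(down, gene), exon), prom))
  l_inter <- total - l_prom - l_exon - l_intron - l_down
  c(promoter = l_prom, exon = l_exon, intron = l_intron,
    downstream = l_down, intergenic = l_inter)
}

#' Region enrichment of repeats relative to genome-length expectation
#'
#' Each repeat is assigned one region by midpoint under the precedence
#' promoter > exon > intron > downstream > intergenic. Per (feature, region),
#' fold enrichment is observed / expected with expected counts proportional
#' to the effective region length, tested by a 1-df chi-square of (in region
#' vs not) against the length proportion, BH-corrected over all tests.
#'
#' @param repeats Repeat table.
#' @param model A [region_model()].
#' @param level `"name"`, `"family"` or `"klass"`.
#' @return `data.table`: `feature`, `region`, `n_obs`, `n_exp`, `fold`,
#'   `chi2`, `p`, `fdr`.
#' @export
region_enrichment <- function(repeats, model, level = c("family", "name", "klass")) {
  level <- match.arg(level)
  r <- data.table::as.data.table(repeats)
  mid <- r$start + (r$end - r$start) %/% 2L
  reg <- rep(NA_character_, nrow(r))
  for (chr in unique(r$chrom)) {
    i <- r$chrom == chr
    reg[i] <- classify_positions(model, chr, mid[i])
  }
  r[, "region" := reg]
  r[, "feature" := r[[level]]]
  lens <- model$region_lengths
  lens <- lens[lens > 0]
  total <- sum(lens)
  res <- list()
  for (feature in sort(unique(r$feature))) {
    n_f <- sum(r$feature == feature)
    for (region in names(lens)) {
      n_obs <- sum(r$feature == feature & r$region == region)
      p_len <- lens[[region]] / total
      n_exp <- n_f * p_len
      cs <- suppressWarnings(stats::chisq.test(c(n_obs, n_f - n_obs),
                                               p = c(p_len, 1 - p_len)))
      res[[length(res) + 1L]] <- data.table::data.table(
        feature = feature, region = region, n_obs = n_obs, n_exp = n_exp,
        fold = n_obs / n_exp, chi2 = unname(cs$statistic),
        p = unname(cs$p.value))
    }
  }
  out <- data.table::rbindlist(res)
  out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  out[]
}

#' Strand preference of repeats relative to their host gene
#'
#' Each repeat whose midpoint lies in the chosen region of exactly one gene
#' contributes same/opposite by strand match with that gene; repeats hitting
#' genes on both strands are excluded. Per repeat name, a chi-square against
#' the 50:50 null, BH FDR across names.
#'
#' @param repeats Repeat table.
#' @param regions Interval `data.table` with `chrom`, `start`, `end`,
#'   `strand`, `gene_id` (e.g. `model$promoter` or gene spans from a
#'   [region_model()]).
#' @param min_total Names with fewer assigned copies are skipped (default 10).
#' @return `data.table`: `name`, `n_same`, `n_opposite`, `ratio`, `chi2`,
#'   `p`, `fdr`.
#' @export
strand_preference <- function(repeats, regions, min_total = 10L) {
  r <- data.table::as.data.table(repeats)
  mid <- r$start + (r$end - r$start) %/% 2L
  midq <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  ov <- GenomicRanges::findOverlaps(midq, as_granges0(regions, use_strand = FALSE),
                                    ignore.strand = TRUE)
  h <- data.table::data.table(rep_idx = S4Vectors::queryHits(ov),
                              gene_strand = regions$strand[S4Vectors::subjectHits(ov)])
  h <- unique(h)
  # drop repeats hitting genes on both strands
  ns <- h[, list(n_strands = data.table::uniqueN(gene_strand)), by = "rep_idx"]
  h <- h[h$rep_idx %in% ns$rep_idx[ns$n_strands == 1L]]
  h <- unique(h)
  h[, "same" := r$strand[h$rep_idx] == h$gene_strand]
  h[, "name" := r$name[h$rep_idx]]
  res <- h[, {
    n_same <- sum(same); n_opp <- .N - n_same
    if (.N >= min_total) {
      cs <- suppressWarnings(stats::chisq.test(c(n_same, n_opp),
                                               p = c(0.5, 0.5)))
      list(n_same = n_same, n_opposite = n_opp,
           ratio = if (n_opp > 0) n_same / n_opp else NA_real_,
           chi2 = unname(cs$statistic), p = unname(cs$p.value))
    } else NULL
  }, by = "name"]
  if (nrow(res) > 0L) res[, "fdr" := stats::p.adjust(res$p, method = "BH")]
  data.table::setorder(res, name)
  res[]
}
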