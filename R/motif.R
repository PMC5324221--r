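# PWM scanning of proximal promoter sequences and repeat consensus
# sequences; group-wise ANOVA of maximal log-odds scores across
# fold-change-ranked gene groups. Scores are in bits (log2 odds against the
# background); site counts use a similarity threshold tau = fraction of the
# maximal achievable score.

#' Construct a position weight matrix object
#'
#' @param matrix L x 4 matrix of per-position base probabilities (columns
#'   A, C, G, T); rows are renormalised to sum to 1.
#' @param motif_id Motif identifier.
#' @param tf_names Character vector of TFs binding the motif.
#' @param background Length-4 background probabilities (default uniform).
#' @return A `pwm` object (list with `motif_id`, `tf_names`, `matrix`,
#'   `background`).
#' @export
pwm <- function(matrix, motif_id = "motif", tf_names = character(0),
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 1L, all(matrix >= 0))
  matrix <- matrix / rowSums(matrix)
  colnames(matrix) <- c("A", "C", "G", "T")
  stopifnot(abs(sum(background) - 1) < 1e-6)
  structure(list(motif_id = motif_id, tf_names = tf_names, matrix = matrix,
                 background = stats::setNames(as.numeric(background),
                                              c("A", "C", "G", "T"))),
            class = "pwm")
}

#' Log-odds score matrix of a PWM, in bits
#'
#' `score(i, b) = log2((p(i, b) + pc * bg_b) / ((1 + pc) * bg_b))`. The
#' maximal achievable score is the sum over positions of the row maxima.
#'
#' @param pwm A `pwm` object.
#' @param pseudocount Per-cell pseudocount weight (default 0.01).
#' @return L x 4 numeric matrix with attribute `max_score`.
#' @export
log_odds <- function(pwm, pseudocount = 0.01) {
  bg <- matrix(pwm$background, nrow = nrow(pwm$matrix), ncol = 4L,
               byrow = TRUE)
  s <- log2((pwm$matrix + pseudocount * bg) / ((1 + pseudocount) * bg))
  colnames(s) <- c("A", "C", "G", "T")
  attr(s, "max_score") <- sum(apply(s, 1, max))
  s
}

# internal: DNA string -> integer codes 1..4 (A,C,G,T), NA for anything else
seq_codes <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  match(chars, c("A", "C", "G", "T"))
}

# internal: per-window log-odds scores of coded sequence; NA where a window
# contains a non-ACGT base
window_scores <- function(codes, S) {
  L <- nrow(S)
  W <- length(codes) - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (i in seq_len(L)) {
    sc <- sc + unname(S[i, ][codes[i:(i + W - 1L)]])
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every window on the forward strand and, when `both_strands`, on the
#' reverse complement; reports the maximal score, its position and strand,
#' and the number of windows scoring at least `tau` times the maximal
#' achievable score (overlapping windows all counted). Windows containing a
#' non-ACGT base are skipped.
#'
#' @param seq A character string or `DNAString` over A/C/G/T/N.
#' @param pwm A `pwm` object.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param tau Similarity threshold for site counting (default 0.9).
#' @param pseudocount Passed to [log_odds()].
#' @return List: `motif_id`, `max_score` (NA when no scorable window),
#'   `n_sites`, `best_pos` (0-based, forward-strand coordinates of window
#'   start), `best_strand`, `max_achievable`.
#' @export
scan_sequence <- function(seq, pwm, both_strands = TRUE, tau = 0.9,
                          pseudocount = 0.01) {
  S <- log_odds(pwm, pseudocount)
  L <- nrow(S)
  codes <- seq_codes(seq)
  n <- length(codes)
  if (n < L) {
    return(list(motif_id = pwm$motif_id, max_score = NA_real_,
                n_sites = NA_integer_, best_pos = NA_integer_,
                best_strand = NA_character_,
                max_achievable = attr(S, "max_score")))
  }
  fwd <- window_scores(codes, S)
  strands <- rep("+", length(fwd))
  pos <- seq_along(fwd) - 1L
  if (both_strands) {
    rc <- rev(5L - codes)  # reverse complement in code space (A<->T, C<->G)
    rev_sc <- window_scores(rc, S)
    # window starting at j (0-based) on rc covers forward positions
    # [n - j - L, n - j) -> forward-strand start n - j - L
    fwd <- c(fwd, rev_sc)
    strands <- c(strands, rep("-", length(rev_sc)))
    pos <- c(pos, n - seq_along(rev_sc) + 1L - 1L - L + 1L)
  }
  ok <- !is.na(fwd)
  if (!any(ok)) {
    return(list(motif_id = pwm$motif_id, max_score = NA_real_,
                n_sites = NA_integer_, best_pos = NA_integer_,
                best_strand = NA_character_,
                max_achievable = attr(S, "max_score")))
  }
  best <- which(ok)[which.max(fwd[ok])]
  thr <- tau * attr(S, "max_score")
  list(motif_id = pwm$motif_id,
       max_score = fwd[best],
       n_sites = sum(fwd[ok] >= thr),
       best_pos = pos[best],
       best_strand = strands[best],
       max_achievable = attr(S, "max_score"))
}

#' Count motif sites in a consensus sequence
#'
#' Number of windows (both strands) scoring at least `tau` times the maximal
#' achievable log-odds score — e.g. binding sites at the 90% similarity level
#' in a repeat consensus.
#'
#' @inheritParams scan_sequence
#' @return Integer site count (NA when the sequence is shorter than the
#'   motif).
#' @export
count_consensus_sites <- function(seq, pwm, tau = 0.9, pseudocount = 0.01) {
  scan_sequence(seq, pwm, both_strands = TRUE, tau = tau,
                pseudocount = pseudocount)$n_sites
}

#' Scan many gene sequences with many PWMs
#'
#' @param seqs Named list/`DNAStringSet` of per-gene sequences (e.g. proximal
#'   promoters).
#' @param pwms Named list of `pwm` objects.
#' @param tau,pseudocount Passed to [scan_sequence()].
#' @return Numeric matrix of max scores, genes x motifs (NA where the
#'   sequence is unscorable).
#' @export
scan_promoters <- function(seqs, pwms, tau = 0.9, pseudocount = 0.01) {
  out <- matrix(NA_real_, nrow = length(seqs), ncol = length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (j in seq_along(pwms)) {
    S <- log_odds(pwms[[j]], pseudocount)
    L <- nrow(S)
    for (i in seq_along(seqs)) {
      codes <- seq_codes(seqs[[i]])
      n <- length(codes)
      if (n < L) next
      sc <- c(window_scores(codes, S), window_scores(rev(5L - codes), S))
      if (any(!is.na(sc))) out[i, j] <- max(sc, na.rm = TRUE)
    }
  }
  out
}

#' One-way ANOVA of max motif scores across gene groups
#'
#' Per motif, a fixed-effects one-way ANOVA of per-gene maximal scores on the
#' group factor, with BH FDR over motifs. Motifs are ranked by FDR, then by
#' the strength of the monotone trend of group means across the ordered
#' groups.
#'
#' @param scores Genes x motifs matrix of max scores (from
#'   [scan_promoters()]).
#' @param groups Named vector gene_id -> ordered group id (1 = highest
#'   fold-change group).
#' @return `data.table`: `motif_id`, `f`, `p`, `fdr`, `trend` (Pearson
#'   correlation of group means with group order), plus `mean.g<k>` columns.
#' @export
group_motif_anova <- function(scores, groups) {
  genes <- intersect(rownames(scores), names(groups))
  g <- factor(groups[genes])
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  res <- lapply(colnames(scores), function(m) {
    y <- scores[genes, m]
    keep <- !is.na(y)
    yk <- y[keep]; gk <- droplevels(g[keep])
    means <- tapply(yk, gk, mean)
    base <- data.table::data.table(motif_id = m)
    if (stats::sd(yk) == 0 || nlevels(gk) < 2L) {
      stat <- data.table::data.table(f = 0, p = 1, trend = NA_real_)
    } else {
      an <- stats::anova(stats::lm(yk ~ gk))
      trend <- if (stats::sd(means) > 0) {
        unname(stats::cor(as.numeric(names(means)), as.numeric(means)))
      } else NA_real_
      stat <- data.table::data.table(f = an$`F value`[1], p = an$`Pr(>F)`[1],
                                     trend = trend)
    }
    mcols <- data.table::as.data.table(
      as.list(stats::setNames(as.numeric(means),
                              paste0("mean.g", names(means)))))
    cbind(base, stat, mcols)
  })
  out <- data.table::rbindlist(res, fill = TRUE)
  out[, "fdr" := stats::p.adjust(out$p, method = "BH")]
  out[, ".trend_rank" := -abs(out$trend)]
  data.table::setorder(out, fdr, .trend_rank, na.last = TRUE)
  out[, ".trend_rank" := NULL]
  out[]
}

#' Prioritise TFs by concordance of motif trend and TF expression
#'
#' Joins motif ANOVA results to the expression of the TFs binding each motif
#' and flags TFs whose own fold-change over the stage pair has the same sign
#' as the motif's enrichment trend toward the top fold-change groups (a
#' negative `trend` means higher scores in the top groups, since group 1 is
#' the most-induced).
#'
#' @param anova_results Output of [group_motif_anova()].
#' @param pwms Named list of `pwm` objects supplying `tf_names`.
#' @param tf_expr An `expr_set` with TF genes in rows.
#' @param from_stage,to_stage Stage pair for the TF's own fold-change.
#' @return `data.table`: `motif_id`, `tf`, `fdr`, `trend`, `tf_log2fc`,
#'   `concordant` (NA when the TF is absent from the expression data), sorted
#'   by (concordant desc, fdr).
#' @export
prioritize_tfs <- function(anova_results, pwms, tf_expr, from_stage, to_stage) {
  if (nrow(anova_results) == 0L) return(data.table::data.table())
  tf_fc <- fold_change(tf_expr, from_stage, to_stage)
  fc_map <- stats::setNames(tf_fc$log2fc, tf_fc$gene_id)
  rows <- list()
  for (i in seq_len(nrow(anova_results))) {
    m <- anova_results$motif_id[i]
    tfs <- pwms[[m]]$tf_names
    if (length(tfs) == 0L) tfs <- NA_character_
    for (tf in tfs) {
      lfc <- if (!is.na(tf) && tf %in% names(fc_map)) fc_map[[tf]] else NA_real_
      trend <- anova_results$trend[i]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        motif_id = m, tf = tf, fdr = anova_results$fdr[i], trend = trend,
        tf_log2fc = lfc,
        concordant = if (is.na(lfc) || is.na(trend)) NA else
          sign(lfc) == sign(-trend))
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -concordant, fdr, na.last = TRUE)
  out[]
}
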