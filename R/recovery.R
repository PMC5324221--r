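# End-to-end parameter recovery against the generator's ground truth: the
# planted per-copy coefficients are estimated by the same promoter-count
# regression a real analysis would run, and compared with the effective
# planted values.

#' One-seed end-to-end regression recovery
#'
#' Simulates a bundle, builds the 2 kb orientation-split promoter count
#' table, computes the stage fold-change of each family's target pair and
#' regresses it on the counts; returns one row per (family, orientation)
#' with the effective planted coefficient it should recover.
#'
#' The planted truth for a (family, orientation) pair is 0 when the family's
#' effect is null or restricted to the other orientation, otherwise the
#' family's `beta_window_effective` (per-copy effect averaged over the
#' distance-decay weight inside the counting window). A pseudocount of 0
#' matches the generator's additive-in-log2 model.
#'
#' @param config A [sim_config()].
#' @param pseudocount Pseudocount for the fold-change (default 0).
#' @return `data.table`: `feature`, `family`, `orientation`, `truth`,
#'   `estimate`, `se`, `p`, `fdr`, `covered` (truth inside the 95% CI),
#'   `sign_ok`.
#' @export
regression_recovery <- function(config = sim_config(), pseudocount = 0) {
  b <- simulate_bundle(config)
  prom <- make_promoters(b$tss, config$count_window, 0L, b$contig_lengths)
  ft <- build_feature_table(prom, b$repeats, level = "name",
                            coverage_families = character(0))
  X <- as.matrix(ft[, grep("[.](same|opposite)$", names(ft)), with = FALSE])
  rownames(X) <- ft$gene_id
  fits <- list()
  rows <- list()
  for (fam in b$truth$families) {
    pair <- paste(fam$target_pair, collapse = ">")
    if (is.null(fits[[pair]])) {
      fc <- fold_change(b$expr, fam$target_pair[1], fam$target_pair[2],
                        pseudocount = pseudocount)
      fits[[pair]] <- multiple_regression(fc, X, min_genes = 5L)
    }
    reg <- fits[[pair]]
    for (orientation in c("same", "opposite")) {
      feature <- paste0("count.name.", fam$name, ".", orientation)
      ri <- which(reg$feature == feature)  # resolved before the [ scope
      if (length(ri) == 0L) next
      row <- reg[ri]
      truth <- if (fam$beta == 0) 0 else
        if (fam$orientation == "same_only" && orientation == "opposite") 0 else
          fam$beta_window_effective
      crit <- stats::qt(0.975, attr(reg, "n") - nrow(reg) - 1L)
      rows[[feature]] <- data.table::data.table(
        feature = feature, family = fam$name, orientation = orientation,
        truth = truth, estimate = row$estimate, se = row$se, p = row$p,
        fdr = row$fdr,
        covered = abs(row$estimate - truth) <= crit * row$se,
        sign_ok = truth == 0 || sign(row$estimate) == sign(truth))
    }
  }
  data.table::rbindlist(rows)
}

#' Multi-seed recovery study
#'
#' Runs [regression_recovery()] across `n_seeds` consecutive seeds and
#' summarises, per (family, orientation): mean estimate, the fraction of
#' seeds in which the planted value lies inside the 95% CI, the fraction
#' with the planted sign, and — for planted-null coefficients — the fraction
#' of seeds with FDR above `null_fdr`.
#'
#' @param n_seeds Number of seeds (default 100).
#' @param base_seed First seed; seeds are `base_seed + 0:(n_seeds-1)`.
#' @param config_fn Function seed -> [sim_config()] (default the package
#'   default configuration).
#' @param null_fdr FDR threshold a planted-null coefficient should exceed
#'   (default 0.1).
#' @return List with `per_seed` (all rows) and `summary` (`data.table` with
#'   `feature`, `truth`, `mean_estimate`, `coverage`, `sign_rate`,
#'   `null_fdr_rate`).
#' @export
recovery_study <- function(n_seeds = 100L, base_seed = 1L,
                           config_fn = function(seed) sim_config(seed = seed),
                           null_fdr = 0.1) {
  per_seed <- data.table::rbindlist(lapply(seq_len(n_seeds), function(i) {
    out <- regression_recovery(config_fn(base_seed + i - 1L))
    out[, "seed" := base_seed + i - 1L]
    out
  }))
  summary <- per_seed[, list(
    truth = truth[1],
    mean_estimate = mean(estimate),
    coverage = mean(covered),
    sign_rate = mean(sign_ok),
    null_fdr_rate = if (truth[1] == 0) mean(fdr > null_fdr) else NA_real_
  ), by = "feature"]
  list(per_seed = per_seed, summary = summary)
}
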