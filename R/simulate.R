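# Seeded generator of a complete, small, self-consistent input bundle:
# annotation, repeats, stage-structured expression with planted per-copy,
# strand-specific, distance-decaying effects on fold-change, motifs and
# (optionally) genome sequence — with full ground truth for recovery tests.

#' Default simulation configuration
#'
#' One 10 Mb chromosome carrying 2000 spaced genes, six developmental stages
#' (zygote through blastocyst) with four samples each, gene archetypes
#' emulating maternal decay, transient 2-cell induction, late activation and
#' flat expression, and three planted repeat families: a SINE-like family
#' (high copy rate, modest both-strand effect, weak distance decay), an
#' LTR-like family (low copy rate, strong same-strand-only effect, sharp
#' decay, same-strand-biased placement near genes) and a LINE-like null
#' family placed away from TSSs.
#'
#' Effects are additive in log2 fold-change units per copy, weighted by
#' `exp(-d / decay_scale)` at the copy's distance to the TSS, and applied to
#' the target stage of each family's stage pair.
#'
#' @param seed RNG seed; every random draw flows from it.
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param min_spacing Minimum distance between adjacent TSSs.
#' @param samples_per_stage Samples per developmental stage.
#' @param noise_sd Per-sample multiplicative noise SD, log2 units.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression
#'   parameters (natural-log scale).
#' @param archetype_fractions Named mixing fractions over the four stage
#'   archetypes (maternal decay, transient 2C, late activation, flat).
#' @param families List of repeat-family descriptors; see the default for the
#'   fields (`name`, `family`, `klass`, `rate` copies/bp, `len_range`,
#'   `strand_rule`, `strand_bias_rho`, `beta` log2FC/copy, `orientation`,
#'   `decay_scale` bp, `target_pair`, `avoid_tss` bp).
#' @param effect_window Upstream window (bp) within which copies exert their
#'   effect.
#' @param count_window Upstream window (bp) used for truth feature counts and
#'   the effective-coefficient calculation.
#' @param emit_sequence Generate genome sequence (with family consensus
#'   written into repeat copies) — needed only for motif scanning.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       chrom_length = 1e7,
                       min_spacing = 3000L,
                       samples_per_stage = 4L,
                       noise_sd = 0.8,
                       baseline_meanlog = 3,
                       baseline_sdlog = 1,
                       families = NULL,
                       archetype_fractions = c(maternal_decay = 0.3,
                                               transient_2C = 0.2,
                                               late_activation = 0.3,
                                               flat = 0.2),
                       effect_window = 10000L,
                       count_window = 2000L,
                       emit_sequence = FALSE) {
  if (is.null(families)) {
    families <- list(
      list(name = "B1_Sim", family = "Alu", klass = "SINE",
           rate = 8e-4, len_range = c(80L, 150L),
           strand_rule = "uniform", strand_bias_rho = NA,
           beta = 0.3, orientation = "both", decay_scale = 5000,
           target_pair = c("mid2C", "late2C"), avoid_tss = 0L),
      list(name = "MT2_Sim", family = "ERVL", klass = "LTR",
           rate = 1e-4, len_range = c(300L, 500L),
           strand_rule = "gene_same_biased", strand_bias_rho = 0.8,
           beta = 1.2, orientation = "same_only", decay_scale = 800,
           target_pair = c("early2C", "mid2C"), avoid_tss = 0L),
      list(name = "L1_Sim", family = "L1", klass = "LINE",
           rate = 2e-4, len_range = c(500L, 2000L),
           strand_rule = "uniform", strand_bias_rho = NA,
           beta = 0, orientation = "both", decay_scale = Inf,
           target_pair = c("mid2C", "late2C"), avoid_tss = 5000L,
           avoid_keep_prob = 0.3)
    )
  }
  structure(list(
    seed = as.integer(seed),
    chroms = stats::setNames(chrom_length, "chrS"),
    n_genes = as.integer(n_genes),
    min_spacing = as.integer(min_spacing),
    stages = c("zygote", "early2C", "mid2C", "late2C", "eightC", "blast"),
    samples_per_stage = as.integer(samples_per_stage),
    archetypes = list(
      maternal_decay = c(8, 6, 3, 1, 0.5, 0.25),
      transient_2C = c(0.2, 0.5, 8, 6, 0.5, 0.2),
      late_activation = c(0.2, 0.2, 0.5, 2, 6, 8),
      flat = c(1, 1, 1, 1, 1, 1)),
    archetype_fractions = archetype_fractions,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    noise_sd = noise_sd,
    families = families,
    effect_window = as.integer(effect_window),
    count_window = as.integer(count_window),
    emit_sequence = emit_sequence
  ), class = "sim_config")
}

# internal: random DNA of length n as a character string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# internal: index of the nearest value in a sorted vector, per query
nearest_sorted <- function(q, sorted) {
  i <- findInterval(q, sorted)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(sorted))
  ifelse(abs(q - sorted[lo]) <= abs(sorted[hi] - q), lo, hi)
}

# internal: the planted homeobox-like motif (TAATCC core)
planted_pwm <- function() {
  consensus <- c("T", "A", "A", "T", "C", "C")
  m <- matrix(0.01, nrow = length(consensus), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) m[i, consensus[i]] <- 0.97
  pwm(m, motif_id = "OBXSIM", tf_names = "ObxSim")
}

#' Generate a synthetic input bundle
#'
#' Places gene TSSs uniformly with a minimum spacing, drops repeat copies by
#' a per-family Poisson process with the family's strand rule, builds the
#' expression matrix as per-gene lognormal baseline x archetype stage
#' profile x `2^(sum of planted copy effects)` at each family's target stage
#' x per-sample lognormal noise, and records full ground truth. With the
#' same config (including seed) the output is reproduced exactly.
#'
#' @param config A [sim_config()].
#' @return A `sim_bundle` list: `config`, `transcripts` (as [read_gtf()]),
#'   `repeats` (as [read_repeatmasker()]), `tss`, `expr` (an `expr_set`),
#'   `truth` (per-family and per-gene ground truth), `pwms`, `consensus`
#'   (per-family consensus sequences, planted motif copies included for the
#'   LTR-like family), `genome` (`DNAStringSet` or NULL), `contig_lengths`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  set.seed(config$seed)
  chrom <- names(config$chroms)[1]
  L <- unname(config$chroms[1])
  n <- config$n_genes
  margin <- 20000L

  slack <- L - 2 * margin - (n - 1) * config$min_spacing
  if (n > 0L && slack <= 0) {
    stop("infeasible spacing: ", n, " genes with min spacing ",
         config$min_spacing, " do not fit in ", L, " bp")
  }

  # --- genes ---
  if (n > 0L) {
    tss <- margin + as.integer(floor(sort(stats::runif(n, 0, slack)))) +
      (seq_len(n) - 1L) * config$min_spacing
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("G%04d", seq_len(n))
    exon1_len <- sample(200:500, n, replace = TRUE)
    intron_len <- sample(500:2000, n, replace = TRUE)
    exon2_len <- sample(500:1500, n, replace = TRUE)
    span <- exon1_len + intron_len + exon2_len
    e1s <- ifelse(strand == "+", tss, tss - exon1_len + 1L)
    e1e <- e1s + exon1_len
    e2s <- ifelse(strand == "+", e1e + intron_len, e1s - intron_len - exon2_len)
    e2e <- e2s + exon2_len
    starts <- pmin(e1s, e2s); ends <- pmax(e1e, e2e)
    transcripts <- data.table::data.table(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      chrom = chrom, strand = strand,
      start = as.integer(starts), end = as.integer(ends),
      tss = as.integer(tss),
      exon_starts = lapply(seq_len(n), function(i) {
        as.integer(sort(c(e1s[i], e2s[i])))
      }),
      exon_ends = lapply(seq_len(n), function(i) {
        as.integer(sort(c(e1e[i], e2e[i])))
      }))
  } else {
    tss <- integer(0); strand <- character(0); gene_id <- character(0)
    transcripts <- data.table::data.table(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0), start = integer(0),
      end = integer(0), tss = integer(0), exon_starts = list(),
      exon_ends = list())
  }

  # --- repeats ---
  rep_list <- list()
  for (fam in config$families) {
    n_cop <- stats::rpois(1, fam$rate * L)
    if (n_cop == 0L) next
    st <- as.integer(floor(stats::runif(n_cop, 0, L - max(fam$len_range) - 1)))
    len <- sample(fam$len_range[1]:fam$len_range[2], n_cop, replace = TRUE)
    en <- st + len
    if (fam$avoid_tss > 0L && n > 0L) {
      # depletion (not exclusion) near TSSs: copies within avoid_tss of a
      # TSS are retained with probability avoid_keep_prob
      keep_prob <- if (is.null(fam$avoid_keep_prob)) 0 else fam$avoid_keep_prob
      midc <- st + len %/% 2L
      near <- abs(midc - tss[nearest_sorted(midc, tss)]) < fam$avoid_tss
      keep <- !near | stats::runif(n_cop) < keep_prob
      st <- st[keep]; en <- en[keep]
      n_cop <- length(st)
      if (n_cop == 0L) next
    }
    if (fam$strand_rule == "gene_same_biased" && n > 0L) {
      midc <- st + (en - st) %/% 2L
      nearest <- nearest_sorted(midc, tss)
      same <- stats::runif(n_cop) < fam$strand_bias_rho
      rs <- ifelse(same, strand[nearest],
                   ifelse(strand[nearest] == "+", "-", "+"))
    } else {
      rs <- sample(c("+", "-"), n_cop, replace = TRUE)
    }
    rep_list[[fam$name]] <- data.table::data.table(
      chrom = chrom, start = st, end = en, strand = rs,
      name = fam$name, family = fam$family, klass = fam$klass,
      divergence = round(stats::runif(n_cop, 0, 25), 1),
      ambiguous_class = FALSE)
  }
  repeats <- data.table::rbindlist(rep_list)
  if (nrow(repeats) > 0L) {
    data.table::setorder(repeats, chrom, start, end, name)
    repeats[, "element_id" := seq_len(nrow(repeats))]
    data.table::setcolorder(repeats, c("chrom", "start", "end", "strand",
                                       "name", "family", "klass",
                                       "element_id", "divergence",
                                       "ambiguous_class"))
  } else {
    repeats <- data.table::data.table(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), name = character(0), family = character(0),
      klass = character(0), element_id = integer(0), divergence = numeric(0),
      ambiguous_class = logical(0))
  }

  tss_map <- data.table::data.table(gene_id = gene_id, chrom = chrom,
                                    strand = strand, tss = as.integer(tss))
  data.table::setorder(tss_map, chrom, tss, gene_id)

  # --- planted effects: per gene x family, copies within the upstream
  # effect window contribute beta * exp(-d / decay_scale), subject to the
  # family's orientation rule ---
  fam_names <- vapply(config$families, `[[`, character(1), "name")
  effects <- matrix(0, nrow = n, ncol = length(fam_names),
                    dimnames = list(tss_map$gene_id, fam_names))
  counts_same <- counts_opp <- matrix(
    0L, nrow = n, ncol = length(fam_names),
    dimnames = list(tss_map$gene_id, fam_names))
  if (n > 0L && nrow(repeats) > 0L) {
    eff_prom <- make_promoters(tss_map, config$effect_window, 0L,
                               config$chroms)
    cnt_prom <- make_promoters(tss_map, config$count_window, 0L,
                               config$chroms)
    for (fi in seq_along(config$families)) {
      fam <- config$families[[fi]]
      fr <- repeats[repeats$name == fam$name]
      if (nrow(fr) == 0L) next
      h <- overlap_pairs(eff_prom, fr)
      if (nrow(h) > 0L) {
        d <- pmax(distance_to_tss(fr$start[h$rep_idx], fr$end[h$rep_idx],
                                  eff_prom$tss[h$prom_idx],
                                  eff_prom$strand[h$prom_idx]), 0L)
        admissible <- if (fam$orientation == "same_only") {
          fr$strand[h$rep_idx] == eff_prom$strand[h$prom_idx]
        } else rep(TRUE, nrow(h))
        w <- if (is.finite(fam$decay_scale)) exp(-d / fam$decay_scale) else
          rep(1, nrow(h))
        contrib <- fam$beta * w * admissible
        agg <- rowsum(contrib, eff_prom$gene_id[h$prom_idx])
        effects[rownames(agg), fam$name] <-
          effects[rownames(agg), fam$name] + agg[, 1]
      }
      hc <- overlap_pairs(cnt_prom, fr)
      if (nrow(hc) > 0L) {
        same <- fr$strand[hc$rep_idx] == cnt_prom$strand[hc$prom_idx]
        gs <- cnt_prom$gene_id[hc$prom_idx]
        ts <- rowsum(as.integer(same), gs)
        to <- rowsum(as.integer(!same), gs)
        counts_same[rownames(ts), fam$name] <- ts[, 1]
        counts_opp[rownames(to), fam$name] <- to[, 1]
      }
    }
  }

  # --- expression ---
  stages <- config$stages
  n_samp <- length(stages) * config$samples_per_stage
  sample_names <- paste0(rep(stages, each = config$samples_per_stage), "_",
                         rep(seq_len(config$samples_per_stage),
                             times = length(stages)))
  design <- data.table::data.table(
    sample = sample_names,
    stage = rep(stages, each = config$samples_per_stage))
  arch_mat <- do.call(rbind, config$archetypes)
  colnames(arch_mat) <- stages
  if (n > 0L) {
    baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    archetype <- sample(names(config$archetypes), n, replace = TRUE,
                        prob = config$archetype_fractions)
    stage_effect <- matrix(0, nrow = n, ncol = length(stages),
                           dimnames = list(tss_map$gene_id, stages))
    for (fi in seq_along(config$families)) {
      fam <- config$families[[fi]]
      to_stage <- fam$target_pair[2]
      stage_effect[, to_stage] <- stage_effect[, to_stage] +
        effects[, fam$name]
    }
    noise <- matrix(stats::rnorm(n * n_samp, 0, config$noise_sd),
                    nrow = n, ncol = n_samp)
    mat <- matrix(0, nrow = n, ncol = n_samp,
                  dimnames = list(tss_map$gene_id, sample_names))
    for (j in seq_len(n_samp)) {
      s <- design$stage[j]
      mat[, j] <- baseline * arch_mat[archetype, s] *
        2^(stage_effect[, s]) * 2^(noise[, j])
    }
  } else {
    baseline <- numeric(0); archetype <- character(0)
    mat <- matrix(0, nrow = 0, ncol = n_samp,
                  dimnames = list(character(0), sample_names))
  }
  expr <- expr_set(mat, design, stage_order = stages)

  # --- motifs & consensus sequences ---
  motif <- planted_pwm()
  consensus <- character(0)
  consensus_sites <- integer(0)
  for (fam in config$families) {
    clen <- as.integer(mean(fam$len_range))
    # G/C-only background: the TAATCC core and its reverse complement both
    # need A and T, so the planted site count is exact by construction
    seq <- paste(sample(c("G", "C"), clen, replace = TRUE), collapse = "")
    n_plant <- if (fam$klass == "LTR") 3L else 0L
    if (n_plant > 0L) {
      core <- "TAATCC"
      at <- as.integer(seq(10, clen - nchar(core) - 10,
                           length.out = n_plant))
      for (p in at) {
        substr(seq, p, p + nchar(core) - 1L) <- core
      }
    }
    consensus[fam$name] <- seq
    consensus_sites[fam$name] <- n_plant
  }

  genome <- NULL
  if (isTRUE(config$emit_sequence)) {
    # build on a character vector; string replacement on a multi-Mb string
    # would copy the whole chromosome per repeat
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (i in seq_len(nrow(repeats))) {
      cs <- consensus[[repeats$name[i]]]
      w <- repeats$end[i] - repeats$start[i]
      ins <- substr(strrep(cs, ceiling(w / nchar(cs))), 1L, w)
      if (repeats$strand[i] == "-") {
        ins <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ins)))
      }
      chars[(repeats$start[i] + 1L):repeats$end[i]] <- strsplit(ins, "")[[1]]
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chars, collapse = ""), chrom))
  }

  truth <- list(
    seed = config$seed,
    families = lapply(config$families, function(fam) {
      # expected per-copy effect of a copy counted in the count_window:
      # copies are extended intervals, so the nearest-base distance has an
      # atom at 0 (mass ~ mean_len / (W + mean_len)) plus a uniform part
      W <- config$count_window
      mean_len <- mean(fam$len_range)
      eff <- if (is.finite(fam$decay_scale)) {
        fam$beta * (mean_len + fam$decay_scale * (1 - exp(-W / fam$decay_scale))) /
          (W + mean_len)
      } else fam$beta
      list(name = fam$name, family = fam$family, klass = fam$klass,
           beta = fam$beta, beta_window_effective = eff,
           orientation = fam$orientation, decay_scale = fam$decay_scale,
           strand_rule = fam$strand_rule,
           strand_bias_rho = fam$strand_bias_rho,
           target_pair = fam$target_pair,
           consensus_planted_sites = unname(consensus_sites[fam$name]))
    }),
    genes = data.table::data.table(
      gene_id = tss_map$gene_id, archetype = archetype,
      baseline = baseline),
    counts_same = counts_same,
    counts_opposite = counts_opp,
    effects = effects
  )

  structure(list(config = config, transcripts = transcripts,
                 repeats = repeats, tss = tss_map, expr = expr,
                 truth = truth, pwms = stats::setNames(list(motif),
                                                       motif$motif_id),
                 consensus = consensus, genome = genome,
                 contig_lengths = config$chroms),
            class = "sim_bundle")
}

# internal: GTF emitter for the generated annotation (1-based closed on disk)
sim_write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tx$gene_id, tx$transcript_id)
    lines <- c(lines,
               paste(tx$chrom, "sim", "transcript", tx$start + 1L, tx$end,
                     ".", tx$strand, ".", attr_str, sep = "\t"))
    es <- tx$exon_starts[[1]]; ee <- tx$exon_ends[[1]]
    for (k in seq_along(es)) {
      lines <- c(lines,
                 paste(tx$chrom, "sim", "exon", es[k] + 1L, ee[k], ".",
                       tx$strand, ".", attr_str, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Emits `genes.gtf`, `repeats.out`, `repeats.bed`, `expression.tsv`,
#' `design.tsv`, `motifs.meme`, `truth.json` and, when sequence was
#' generated, `genome.fasta` — all parseable by the package's readers.
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param outdir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gtf = file.path(outdir, "genes.gtf"),
    rmsk = file.path(outdir, "repeats.out"),
    bed = file.path(outdir, "repeats.bed"),
    expr = file.path(outdir, "expression.tsv"),
    design = file.path(outdir, "design.tsv"),
    meme = file.path(outdir, "motifs.meme"),
    truth = file.path(outdir, "truth.json"))
  sim_write_gtf(bundle$transcripts, paths["gtf"])
  write_repeatmasker(bundle$repeats, paths["rmsk"])
  write_bed(bundle$repeats[, list(chrom, start, end, name, score = 0L, strand)],
            paths["bed"])
  em <- data.table::data.table(gene_id = rownames(bundle$expr$mat))
  em <- cbind(em, data.table::as.data.table(bundle$expr$mat))
  data.table::fwrite(em, paths["expr"], sep = "\t", quote = FALSE)
  data.table::fwrite(bundle$expr$design, paths["design"], sep = "\t",
                     quote = FALSE)
  write_meme(bundle$pwms, paths["meme"])
  truth <- bundle$truth
  truth$counts_same <- as.data.frame(truth$counts_same)
  truth$counts_opposite <- as.data.frame(truth$counts_opposite)
  truth$effects <- as.data.frame(truth$effects)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$genome)) {
    paths["fasta"] <- file.path(outdir, "genome.fasta")
    Biostrings::writeXStringSet(bundle$genome, paths["fasta"])
  }
  invisible(paths)
}
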