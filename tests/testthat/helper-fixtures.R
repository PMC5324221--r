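# Fixtures are built in code at test time; nothing binary is stored.

# tiny GTF text: list of (chrom, start1, end1, strand, gene, tx) exon rows,
# 1-based closed as on disk
gtf_text <- function(rows) {
  vapply(rows, function(r) {
    paste(r$chrom, "src", "exon", r$start, r$end, ".", r$strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx),
          sep = "\t")
  }, character(1))
}

write_gtf_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(gtf_text(rows), path)
  path
}

# RepeatMasker .out fixture with the standard 15 columns
rmsk_text <- function(rows) {
  hdr <- c("   SW  perc perc perc  query  position in query  matching repeat",
           "score  div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
           "")
  body <- vapply(rows, function(r) {
    sprintf("  463 %5.1f  0.6  1.7  %s %d %d (0) %s  %s  %s  1  %d  (0)  %d",
            r$div, r$chrom, r$begin, r$end, r$strand, r$name, r$cf,
            r$end - r$begin + 1L, r$id)
  }, character(1))
  c(hdr, body)
}

write_rmsk_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".out", .local_envir = parent.frame())
  writeLines(rmsk_text(rows), path)
  path
}

# small expression matrix + design on disk
write_expr_fixture <- function(mat, design) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  mpath <- file.path(dir, "expr.tsv")
  dpath <- file.path(dir, "design.tsv")
  dt <- data.table::data.table(gene_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, mpath, sep = "\t", quote = FALSE)
  data.table::fwrite(design, dpath, sep = "\t", quote = FALSE)
  list(matrix = mpath, design = dpath)
}

# brute-force half-open overlap: any shared base
bf_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# quick expr_set constructor
make_expr <- function(mat, stages) {
  design <- data.table::data.table(sample = colnames(mat), stage = stages)
  expr_set(mat, design)
}

# a small but non-trivial simulated bundle for module tests
small_config <- function(seed = 1L, n_genes = 200L, ...) {
  sim_config(seed = seed, n_genes = n_genes, chrom_length = 2e6,
             min_spacing = 3000L, ...)
}

# independent PWM oracle: score every window directly from the log-odds
# matrix, both strands
oracle_scan <- function(seq, S) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  L <- nrow(S)
  best <- -Inf
  for (strand in c("+", "-")) {
    x <- if (strand == "+") chars else rev(unname(comp[chars]))
    for (i in seq_len(length(x) - L + 1)) {
      win <- x[i:(i + L - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- sum(S[cbind(seq_len(L), match(win, c("A", "C", "G", "T")))])
      best <- max(best, sc)
    }
  }
  best
}

rand_pwm <- function(L) {
  m <- matrix(stats::rgamma(L * 4, 1), ncol = 4)
  pwm(m / rowSums(m), motif_id = "rnd")
}

# independent UPGMA (average linkage) on a dissimilarity matrix: returns the
# sorted sequence of merge heights
upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1L)) {
        a <- members[[active[i]]]; b <- members[[active[j]]]
        h <- mean(d[a, b])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- c(members[[active[best[1]]]], members[[active[best[2]]]])
    members[[length(members) + 1L]] <- merged
    active <- c(active[-best], length(members))
    heights <- c(heights, best_h)
  }
  sort(heights)
}
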