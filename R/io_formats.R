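# Readers/writers for the external formats the pipeline touches. Everything is
# normalised to ONE internal convention: 0-based half-open intervals held in
# plain data.tables. GTF and RepeatMasker are 1-based closed on disk; BED is
# native. Conversion happens only here, at the I/O boundary.

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF and assembles one record per transcript from
#' its exon lines. Coordinates are converted from the GTF's 1-based closed
#' convention to 0-based half-open. The TSS is the start of the first exon in
#' gene orientation: the 0-based start of the leftmost exon on the `+` strand,
#' and `end - 1` of the rightmost exon on the `-` strand.
#'
#' @param path Path to a GTF file.
#' @return A `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (transcript span, 0-based
#'   half-open), `tss`, and list columns `exon_starts`, `exon_ends` (sorted,
#'   0-based half-open). Rows are ordered by (chrom, start, gene_id,
#'   transcript_id).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    stop("malformed GTF line ", body[which(nfield < 9)[1]], " in ", path,
         ": fewer than 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$gene_id) || is.null(meta$transcript_id)) {
    stop("GTF attributes must contain gene_id and transcript_id: ", path)
  }
  is_exon <- meta$type == "exon"
  tx_declared <- unique(stats::na.omit(meta$transcript_id))
  ex <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    gene_id = meta$gene_id[is_exon],
    transcript_id = meta$transcript_id[is_exon]
  )
  if (nrow(ex) == 0L) stop("no exon records in ", path)
  no_exons <- setdiff(tx_declared, unique(ex$transcript_id))
  if (length(no_exons) > 0L) {
    stop("transcript(s) with no exons in ", path, ": ",
         paste(no_exons, collapse = ", "))
  }
  data.table::setorder(ex, chrom, start, end)
  tx <- ex[, {
    if (any(start[-1] < end[-.N])) {
      stop("overlapping exons in transcript ", transcript_id[1])
    }
    list(
      gene_id = gene_id[1],
      chrom = chrom[1],
      strand = strand[1],
      start = start[1],
      end = end[.N],
      tss = if (strand[1] == "+") start[1] else end[.N] - 1L,
      exon_starts = list(start),
      exon_ends = list(end)
    )
  }, by = transcript_id]
  data.table::setorder(tx, chrom, start, gene_id, transcript_id)
  data.table::setcolorder(tx, c("transcript_id", "gene_id", "chrom", "strand",
                                "start", "end", "tss"))
  tx[]
}

#' Read repeat annotation from a RepeatMasker .out file
#'
#' Parses the UCSC/RepeatMasker `.out` dialect (3 header lines, whitespace
#' aligned columns). The `C` strand symbol is mapped to `-`; 1-based closed
#' genomic positions become 0-based half-open. The combined `class/family`
#' field is split into `klass` and `family` (a field without `/` fills both).
#' Records whose class contains `?` are retained and flagged in
#' `ambiguous_class`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `family`, `klass`, `element_id`, `divergence`, `ambiguous_class`.
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), name = character(), family = character(),
      klass = character(), element_id = integer(), divergence = numeric(),
      ambiguous_class = logical()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- lengths(fields)
  if (any(n < 11L)) {
    stop("malformed RepeatMasker line (", which(n < 11L)[1] + 3L,
         "): fewer than 11 columns")
  }
  pick <- function(i) vapply(fields, `[`, character(1), i)
  begin <- suppressWarnings(as.integer(pick(6)))
  end <- suppressWarnings(as.integer(pick(7)))
  if (anyNA(begin) || anyNA(end)) {
    stop("non-numeric coordinates in RepeatMasker file at line ",
         which(is.na(begin) | is.na(end))[1] + 3L)
  }
  strand_raw <- pick(9)
  ok <- strand_raw %in% c("+", "C", "-")
  if (!all(ok)) {
    stop("unknown strand symbol '", strand_raw[!ok][1],
         "' in RepeatMasker file at line ", which(!ok)[1] + 3L)
  }
  cf <- pick(11)
  slash <- regexpr("/", cf, fixed = TRUE)
  klass <- ifelse(slash > 0, substr(cf, 1L, slash - 1L), cf)
  family <- ifelse(slash > 0, substring(cf, slash + 1L), cf)
  element_id <- suppressWarnings(as.integer(vapply(
    fields, function(f) if (length(f) >= 15L) f[15] else NA_character_,
    character(1))))
  rr <- data.table::data.table(
    chrom = pick(5),
    start = begin - 1L,
    end = end,
    strand = ifelse(strand_raw == "C", "-", strand_raw),
    name = pick(10),
    family = family,
    klass = klass,
    element_id = element_id,
    divergence = suppressWarnings(as.numeric(pick(2))),
    ambiguous_class = grepl("?", cf, fixed = TRUE)
  )
  if (any(rr$start >= rr$end)) {
    stop("RepeatMasker record with start >= end at line ",
         which(rr$start >= rr$end)[1] + 3L)
  }
  data.table::setorder(rr, chrom, start, end, name)
  rr[]
}

#' Write repeat records as a RepeatMasker .out file
#'
#' Inverse of [read_repeatmasker()]; emits the 3 standard header lines and the
#' columns the reader consumes (other columns are filled with placeholders).
#'
#' @param repeats A repeat `data.table` as returned by [read_repeatmasker()].
#' @param path Output path.
#' @export
write_repeatmasker <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query            matching          repeat                position in repeat",
    "score   div. del. ins.  sequence  begin    end        (left)   repeat            class/family        begin  end    (left)     ID",
    "")
  cf <- ifelse(repeats$klass == repeats$family, repeats$klass,
               paste0(repeats$klass, "/", repeats$family))
  div <- repeats$divergence
  if (is.null(div)) div <- rep(0, nrow(repeats))
  id <- repeats$element_id
  if (is.null(id)) id <- seq_len(nrow(repeats))
  body <- sprintf("%5d %6.1f %4.1f %4.1f  %s %9d %9d (%d) %s  %-16s %-18s %6d %6d (%d) %6d",
                  1000L, ifelse(is.na(div), 0, div), 0, 0,
                  repeats$chrom, repeats$start + 1L, repeats$end, 0L,
                  ifelse(repeats$strand == "-", "C", "+"),
                  repeats$name, cf, 1L, repeats$end - repeats$start, 0L,
                  ifelse(is.na(id), 0L, id))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an expression matrix and its sample design
#'
#' @param path_matrix TSV with a header row of sample ids and gene ids in the
#'   first column; values are nonnegative (FPKM-like).
#' @param path_design TSV mapping `sample` to `stage`; stage order is the order
#'   of first appearance in this file.
#' @return An `expr_set`: a list with `mat` (numeric matrix, genes x samples),
#'   `design` (`data.table` sample/stage) and `stage_order`.
#' @export
read_expression <- function(path_matrix, path_design) {
  m <- data.table::fread(path_matrix, sep = "\t", header = TRUE)
  gene_ids <- as.character(m[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s) in expression matrix: ",
         gene_ids[duplicated(gene_ids)][1])
  }
  mat <- as.matrix(m[, -1, with = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- gene_ids
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression value(s) found")
  design <- data.table::fread(path_design, sep = "\t", header = TRUE,
                              colClasses = "character")
  data.table::setnames(design, 1:2, c("sample", "stage"))
  expr_set(mat, design)
}

#' Construct an expr_set from a matrix and design table
#'
#' @param mat Numeric gene x sample matrix with dimnames.
#' @param design `data.frame`/`data.table` with columns `sample`, `stage`.
#' @param stage_order Optional explicit stage ordering; defaults to order of
#'   first appearance in `design`.
#' @return An `expr_set` list (`mat`, `design`, `stage_order`).
#' @export
expr_set <- function(mat, design, stage_order = NULL) {
  design <- data.table::as.data.table(design)[, c("sample", "stage"), with = FALSE]
  missing <- setdiff(colnames(mat), design$sample)
  if (length(missing) > 0L) {
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  }
  design <- design[design$sample %in% colnames(mat)]
  if (is.null(stage_order)) stage_order <- unique(design$stage)
  if (!all(design$stage %in% stage_order)) {
    stop("stage(s) in design absent from stage_order")
  }
  structure(list(mat = mat, design = design, stage_order = stage_order),
            class = "expr_set")
}

#' Per-stage mean expression
#'
#' @param expr An `expr_set`.
#' @return Numeric matrix, genes x stages (stage order preserved).
#' @export
stage_means <- function(expr) {
  vapply(expr$stage_order, function(s) {
    cols <- expr$design$sample[expr$design$stage == s]
    rowMeans(expr$mat[, cols, drop = FALSE])
  }, numeric(nrow(expr$mat)))
}

#' Read a BED file (BED3/BED6)
#'
#' BED is natively 0-based half-open, matching the internal convention, so no
#' coordinate conversion takes place. A `.` strand means unstranded; such
#' intervals are treated as present on both strands by orientation-split
#' counting.
#'
#' @param path Path to a BED file.
#' @return `data.table` with `chrom`, `start`, `end` and, if present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                           na.strings = NULL)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(bed, nm[seq_len(min(ncol(bed), 6L))])
  if (ncol(bed) > 6L) bed <- bed[, 1:6, with = FALSE]
  bed[, "chrom" := as.character(bed$chrom)]
  if (any(bed$start >= bed$end)) stop("BED interval with start >= end")
  data.table::setorder(bed, chrom, start, end)
  bed[]
}

#' Write intervals as BED
#'
#' @param dt `data.table` with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns; missing fields are written as `.`.
#' @param path Output path.
#' @export
write_bed <- function(dt, path) {
  out <- data.table::data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0L,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, na = ".",
                     quote = FALSE)
  invisible(path)
}

#' Read PWMs from a MEME (minimal) motif file
#'
#' @param path Path to a MEME-format motif file.
#' @return A named list of `pwm` objects: lists with `motif_id`, `tf_names`,
#'   `matrix` (L x 4 probabilities, columns A,C,G,T) and `background`
#'   (length-4 probabilities).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "[[:space:]]+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF", lines)
  pwms <- list()
  for (s in starts) {
    tok <- strsplit(trimws(lines[s]), "[[:space:]]+")[[1]]
    motif_id <- tok[2]
    tf_names <- if (length(tok) >= 3L) strsplit(tok[3], ",")[[1]] else character(0)
    hdr <- grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1]
    if (is.na(hdr)) stop("no letter-probability matrix for motif ", motif_id)
    hdr <- s + hdr
    w <- as.integer(sub(".*w=[[:space:]]*([0-9]+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1L) stop("motif ", motif_id, " has invalid width")
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "[[:space:]]+"),
                                 function(x) as.numeric(x[1:4])))
    colnames(mat) <- c("A", "C", "G", "T")
    pwms[[motif_id]] <- pwm(mat, motif_id = motif_id, tf_names = tf_names,
                            background = bg)
  }
  pwms
}

#' Write PWMs in MEME (minimal) motif format
#'
#' @param pwms Named list of `pwm` objects (see [read_meme()]).
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.6g C %.6g G %.6g T %.6g", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    out <- c(out,
             paste("MOTIF", p$motif_id,
                   if (length(p$tf_names) > 0) paste(p$tf_names, collapse = ",") else p$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(p$matrix)),
             apply(p$matrix, 1, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                    r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a tidy table as TSV
#'
#' Tab-separated, `.` for missing values, floats at 6 significant digits, so
#' outputs diff reproducibly.
#'
#' @param dt A `data.frame`/`data.table`.
#' @param path Output path.
#' @export
write_tsv <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  num <- vapply(dt, is.double, logical(1))
  for (j in which(num)) {
    data.table::set(dt, j = j, value = signif(dt[[j]], 6))
  }
  data.table::fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A `data.table` (`.` read back as NA).
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".")
}

# internal: data.table intervals (0-based half-open) -> GRanges (1-based closed)
as_granges0 <- function(dt, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(dt)) {
    ifelse(dt$strand %in% c("+", "-"), dt$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = strand
  )
}
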