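#' @name coordinates
#' @title Coordinate conventions
#' @description All intervals in this package are 0-based half-open
#' (`[start, end)`, BED convention). GTF input/output is converted at the
#' boundary. The TSS of a minus-strand gene is `end - 1`; "upstream" is
#' always strand-aware. Read anchors for coverage tracks are single base
#' positions (interval midpoints for paired formats).
NULL

read_tab_lines <- function(path) {
  if (!file.exists(path)) ps_stop("file not found: ", path)
  con <- ps_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines[keep]
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

coord_check <- function(start, end, lineno, path) {
  bad_int <- is.na(start) | is.na(end)
  if (any(bad_int))
    ps_stop("non-integer coordinates at line ", lineno[which(bad_int)[1]],
            " of ", path)
  bad <- start >= end | start < 0
  if (any(bad))
    ps_stop("invalid interval (start >= end or start < 0) at line ",
            lineno[which(bad)[1]], " of ", path)
}

#' Read a peak set from BED6 or narrowPeak
#'
#' Returns a data.frame with columns `chrom`, `start`, `end` (0-based
#' half-open), `name`, `score`, `strand` and `summit` (absolute position,
#' `NA` when absent). For narrowPeak, column 10 holds the summit offset
#' relative to `start` (-1 meaning absent). Track/browser/comment lines
#' are skipped; gzip input is transparent.
#'
#' @param path file path.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return peak data.frame.
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  lines <- read_tab_lines(path)
  if (!length(lines)) return(empty_peaks())
  fl <- split_fields(lines)
  need <- if (format == "bed6") 6L else 10L
  nf <- lengths(fl)
  if (any(nf < need))
    ps_stop("expected at least ", need, " tab-separated fields at line ",
            which(nf < need)[1], " of ", path)
  m <- t(vapply(fl, function(f) f[seq_len(need)], character(need)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  coord_check(start, end, seq_along(lines), path)
  df <- data.frame(
    chrom = m[, 1], start = start, end = end,
    name = m[, 4], score = as.numeric(m[, 5]), strand = m[, 6],
    summit = NA_integer_, stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.integer(m[, 10]))
    df$summit <- ifelse(!is.na(off) & off >= 0, start + off, NA_integer_)
    bad <- !is.na(df$summit) & (df$summit < start | df$summit >= end)
    if (any(bad))
      ps_stop("summit outside peak interval at line ", which(bad)[1],
              " of ", path)
  }
  df
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             summit = integer(), stringsAsFactors = FALSE)
}

#' Write a peak set to BED6 or narrowPeak
#'
#' @param peaks peak data.frame as returned by [read_peaks()].
#' @param path output path (`.gz` writes gzip).
#' @param format `"bed6"` or `"narrowPeak"`.
#' @export
write_peaks <- function(peaks, path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  con <- ps_connection(path, "w")
  on.exit(close(con))
  strand <- ifelse(is.na(peaks$strand) | peaks$strand == "", ".", peaks$strand)
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                     peaks$end, peaks$name, format(peaks$score, trim = TRUE),
                     strand)
  } else {
    off <- ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start)
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t0\t-1\t-1\t%d", peaks$chrom,
                     peaks$start, peaks$end, peaks$name,
                     format(peaks$score, trim = TRUE), strand, off)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read gene models from GTF or TSV
#'
#' Gene models carry a strand-aware TSS/TES, exon structure and biotype.
#' The GTF reader consumes `gene` and `exon` features with `gene_id` and
#' `gene_biotype` attributes (1-based inclusive coordinates, converted to
#' 0-based half-open). The TSV dialect has header columns
#' `gene_id chrom start end strand biotype exon_blocks`, already 0-based
#' half-open, with `exon_blocks` a comma-separated list of
#' `start-end` absolute blocks.
#'
#' @param path file path.
#' @param format `"gtf"` or `"tsv"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `tss`, `tes`, `exon_starts`, `exon_ends` (the
#'   last two comma-separated absolute coordinates, sorted).
#' @export
read_gene_models <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) ps_stop("file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (is.null(md$type) || is.null(md$gene_id) || anyNA(md$gene_id))
      ps_stop("GTF record missing gene_id attribute in ", path)
    is_gene <- md$type == "gene"
    is_exon <- md$type == "exon"
    if (!any(is_gene)) ps_stop("no gene features found in ", path)
    bt <- if (!is.null(md$gene_biotype)) md$gene_biotype else
      rep("other", length(gr))
    g <- data.frame(
      gene_id = as.character(md$gene_id[is_gene]),
      chrom = as.character(GenomicRanges::seqnames(gr[is_gene])),
      start = GenomicRanges::start(gr[is_gene]) - 1L,
      end = GenomicRanges::end(gr[is_gene]),
      strand = as.character(GenomicRanges::strand(gr[is_gene])),
      biotype = as.character(bt[is_gene]),
      stringsAsFactors = FALSE)
    ex <- data.frame(
      gene_id = as.character(md$gene_id[is_exon]),
      start = GenomicRanges::start(gr[is_exon]) - 1L,
      end = GenomicRanges::end(gr[is_exon]))
    g$exon_starts <- g$exon_ends <- ""
    for (i in seq_len(nrow(g))) {
      e <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
      if (!nrow(e)) { # gene without exon lines: single full-span exon
        g$exon_starts[i] <- as.character(g$start[i])
        g$exon_ends[i] <- as.character(g$end[i])
        next
      }
      if (any(e$start < g$start[i] | e$end > g$end[i]))
        ps_stop("exon outside gene span for gene ", g$gene_id[i], " in ", path)
      o <- order(e$start)
      g$exon_starts[i] <- paste(e$start[o], collapse = ",")
      g$exon_ends[i] <- paste(e$end[o], collapse = ",")
    }
  } else {
    lines <- read_tab_lines(path)
    if (!length(lines)) ps_stop("empty gene-model TSV: ", path)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("gene_id", "chrom", "start", "end", "strand", "biotype",
              "exon_blocks")
    if (!all(need %in% hdr))
      ps_stop("gene-model TSV must have header columns: ",
              paste(need, collapse = " "))
    body <- lines[-1]
    if (!length(body)) return(finish_genes(empty_genes()))
    fl <- split_fields(body)
    m <- t(vapply(fl, function(f) f[match(need, hdr)], character(7)))
    start <- suppressWarnings(as.integer(m[, 3]))
    end <- suppressWarnings(as.integer(m[, 4]))
    coord_check(start, end, seq_along(body) + 1L, path)
    g <- data.frame(gene_id = m[, 1], chrom = m[, 2], start = start,
                    end = end, strand = m[, 5], biotype = m[, 6],
                    stringsAsFactors = FALSE)
    g$exon_starts <- g$exon_ends <- ""
    for (i in seq_len(nrow(g))) {
      blocks <- strsplit(m[i, 7], ",", fixed = TRUE)[[1]]
      se <- vapply(strsplit(blocks, "-", fixed = TRUE), as.integer,
                   integer(2))
      if (any(se[1, ] < g$start[i] | se[2, ] > g$end[i]))
        ps_stop("exon outside gene span for gene ", g$gene_id[i], " in ", path)
      o <- order(se[1, ])
      g$exon_starts[i] <- paste(se[1, o], collapse = ",")
      g$exon_ends[i] <- paste(se[2, o], collapse = ",")
    }
  }
  if (anyDuplicated(g$gene_id))
    ps_stop("duplicated gene_id in ", path, ": ",
            g$gene_id[anyDuplicated(g$gene_id)])
  if (!all(g$strand %in% c("+", "-")))
    ps_stop("gene models require strand '+' or '-'")
  finish_genes(g)
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), biotype = character(),
             exon_starts = character(), exon_ends = character(),
             stringsAsFactors = FALSE)
}

# derive tss/tes from strand; 0-based half-open internally
finish_genes <- function(g) {
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g[, c("gene_id", "chrom", "start", "end", "strand", "biotype", "tss",
        "tes", "exon_starts", "exon_ends")]
}

#' Write gene models to TSV or GTF
#'
#' @param genes gene-model data.frame from [read_gene_models()].
#' @param path output path.
#' @param format `"tsv"` or `"gtf"`.
#' @export
write_gene_models <- function(genes, path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  con <- ps_connection(path, "w")
  on.exit(close(con))
  blocks <- mapply(function(s, e) {
    ss <- strsplit(s, ",")[[1]]; ee <- strsplit(e, ",")[[1]]
    paste(paste0(ss, "-", ee), collapse = ",")
  }, genes$exon_starts, genes$exon_ends)
  if (format == "tsv") {
    writeLines(c("gene_id\tchrom\tstart\tend\tstrand\tbiotype\texon_blocks",
                 sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s", genes$gene_id,
                         genes$chrom, genes$start, genes$end, genes$strand,
                         genes$biotype, blocks)), con)
  } else {
    out <- character(0)
    for (i in seq_len(nrow(genes))) {
      attr_ <- sprintf('gene_id "%s"; gene_biotype "%s";', genes$gene_id[i],
                       genes$biotype[i])
      out <- c(out, sprintf("%s\tpeakscape\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            genes$chrom[i], genes$start[i] + 1L, genes$end[i],
                            genes$strand[i], attr_))
      ss <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
      ee <- as.integer(strsplit(genes$exon_ends[i], ",")[[1]])
      out <- c(out, sprintf("%s\tpeakscape\texon\t%d\t%d\t.\t%s\t.\t%s",
                            genes$chrom[i], ss + 1L, ee, genes$strand[i],
                            attr_))
    }
    writeLines(out, con)
  }
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track stores per-chromosome sorted read anchor positions
#' (single base per read) and the sequencing depth used for RPKM
#' normalization.
#'
#' @param reads named list of integer position vectors, one per chromosome.
#' @param library_size total mapped reads; defaults to the number of
#'   stored anchors.
#' @param label track name (e.g. "ATAC", "H3K27ac").
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(reads, library_size = NULL, label = "track") {
  reads <- lapply(reads, function(r) sort(as.numeric(r)))
  n <- sum(lengths(reads))
  if (is.null(library_size)) library_size <- n
  if (library_size <= 0) ps_stop("library_size must be positive")
  if (library_size < n)
    ps_stop("library_size (", library_size, ") smaller than stored reads (",
            n, ")")
  structure(list(reads = reads, library_size = library_size, label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d reads on %d chromosome(s), library size %g\n",
              x$label, sum(lengths(x$reads)), length(x$reads),
              x$library_size))
  invisible(x)
}

#' Read a coverage track
#'
#' `readbed` files carry one read anchor interval per line (BED3+); the
#' anchor is the interval midpoint. `bedgraph` files are expanded to one
#' synthetic anchor per count unit, placed at the bin midpoint.
#'
#' @param path file path.
#' @param format `"readbed"` or `"bedgraph"`.
#' @param library_size optional total read count override.
#' @param label track name.
#' @return [coverage_track()] object.
#' @export
read_coverage <- function(path, format = c("readbed", "bedgraph"),
                          library_size = NULL, label = "track") {
  format <- match.arg(format)
  lines <- read_tab_lines(path)
  if (!length(lines))
    return(coverage_track(list(), library_size = library_size %||% 1,
                          label = label))
  fl <- split_fields(lines)
  nf <- if (format == "bedgraph") 4L else 3L
  if (any(lengths(fl) < nf))
    ps_stop("expected ", nf, " fields at line ", which(lengths(fl) < nf)[1],
            " of ", path)
  m <- t(vapply(fl, function(f) f[seq_len(nf)], character(nf)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  chrom <- m[, 1]
  if (format == "readbed") {
    anchors <- floor((start + end) / 2)
  } else {
    val <- suppressWarnings(as.numeric(m[, 4]))
    if (any(is.na(val) | val < 0))
      ps_stop("negative or invalid coverage value at line ",
              which(is.na(val) | val < 0)[1], " of ", path)
    cnt <- round(val)
    keep <- cnt > 0
    chrom <- rep(chrom[keep], cnt[keep])
    anchors <- rep(floor((start[keep] + end[keep]) / 2), cnt[keep])
  }
  coverage_track(split(anchors, chrom), library_size = library_size,
                 label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coverage track as read-anchor BED
#'
#' @param track [coverage_track()] object.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- ps_connection(path, "w")
  on.exit(close(con))
  for (ch in names(track$reads)) {
    r <- track$reads[[ch]]
    if (length(r))
      writeLines(sprintf("%s\t%d\t%d", ch, as.integer(r), as.integer(r) + 1L),
                 con)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `fdr`,
#' `mean_count_control`, `mean_count_mutant`. `log2fc` is the log2 fold
#' change of the mutant relative to the control genotype, so genes
#' activated by the factor carry negative values.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) ps_stop("file not found: ", path)
  con <- ps_connection(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot_cols(df, c("gene_id", "log2fc", "fdr", "mean_count_control",
                       "mean_count_mutant"), "DE table")
  validate_de_table(df)
}

validate_de_table <- function(df) {
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    ps_stop("duplicated gene_id in DE table: ", paste(dup, collapse = ", "))
  if (any(is.na(df$fdr)) || any(df$fdr < 0 | df$fdr > 1))
    ps_stop("fdr values must lie in [0, 1]")
  if (any(df$mean_count_control < 0 | df$mean_count_mutant < 0))
    ps_stop("mean counts must be non-negative")
  df
}

#' Write a differential-expression table
#' @param de DE data.frame.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  con <- ps_connection(path, "w")
  on.exit(close(con))
  utils::write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV `chrom<TAB>length`.
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_tab_lines(path)
  fl <- split_fields(lines)
  sizes <- vapply(fl, function(f) as.numeric(f[2]), numeric(1))
  names(sizes) <- vapply(fl, `[`, character(1), 1)
  if (any(is.na(sizes) | sizes <= 0)) ps_stop("invalid chromosome length in ", path)
  sizes
}
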