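IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

#' Scan a sequence for an IUPAC consensus motif on both strands
#'
#' Matches the pattern exactly (no mismatches by default) against the
#' plus strand and matches its reverse complement for minus-strand hits;
#' all coordinates are reported on the forward strand, 0-based.
#' Overlapping hits are all reported. An `N` in the subject sequence
#' matches only `N` positions of the pattern.
#'
#' @param seq nucleotide string over `A C G T N`, case-insensitive.
#' @param pattern IUPAC consensus; defaults to the HNF-1beta consensus
#'   `GGTTAATNATTAAC`.
#' @param max_mismatch number of tolerated mismatching positions.
#' @return data.frame with `start` (0-based), `strand`, `matched`.
#' @export
scan_consensus <- function(seq, pattern = "GGTTAATNATTAAC",
                           max_mismatch = 0) {
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    ps_stop("invalid character '", chars[bad[1]], "' at offset ", bad[1] - 1)
  hits_p <- iupac_match(chars, toupper(pattern), max_mismatch)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(pattern))))
  hits_m <- iupac_match(chars, rc, max_mismatch)
  m <- nchar(pattern)
  res <- rbind(
    if (length(hits_p)) data.frame(start = hits_p - 1L, strand = "+"),
    if (length(hits_m)) data.frame(start = hits_m - 1L, strand = "-"))
  if (is.null(res))
    return(data.frame(start = integer(), strand = character(),
                      matched = character(), stringsAsFactors = FALSE))
  res$matched <- vapply(res$start, function(st)
    substr(s, st + 1, st + m), character(1))
  res[order(res$start, res$strand), , drop = FALSE]
}

# 1-based start positions where pattern (IUPAC) matches the subject
# character vector; vectorized sliding comparison, O(n * m)
iupac_match <- function(chars, pattern, max_mismatch = 0) {
  m <- nchar(pattern)
  n <- length(chars)
  if (n < m) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  if (!all(pc %in% names(IUPAC_SETS)))
    ps_stop("invalid IUPAC code in pattern: ",
            pc[!pc %in% names(IUPAC_SETS)][1])
  idx <- seq_len(n - m + 1)
  mism <- integer(length(idx))
  for (j in seq_len(m)) {
    ok <- chars[idx + j - 1] %in% IUPAC_SETS[[pc[j]]]
    mism <- mism + !ok
  }
  idx[mism <= max_mismatch]
}

#' Per-peak motif occurrence
#'
#' Extracts each peak's sequence from the genome and counts consensus
#' hits on both strands.
#'
#' @param peaks peak data.frame.
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @inheritParams scan_consensus
#' @return list with `per_peak` (data.frame `name`, `n_hits`) and
#'   `fraction_with_motif`.
#' @export
peaks_with_motif <- function(peaks, genome, pattern = "GGTTAATNATTAAC",
                             max_mismatch = 0) {
  seqs <- load_genome(genome)
  n_hits <- integer(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[k]
    if (!ch %in% names(seqs)) ps_stop("chromosome not in genome: ", ch)
    if (peaks$end[k] > nchar(seqs[[ch]]))
      ps_stop("peak ", peaks$name[k], " extends beyond chromosome end")
    sub <- substr(seqs[[ch]], peaks$start[k] + 1, peaks$end[k])
    n_hits[k] <- nrow(scan_consensus(sub, pattern, max_mismatch))
  }
  list(per_peak = data.frame(name = peaks$name, n_hits = n_hits,
                             stringsAsFactors = FALSE),
       fraction_with_motif = if (nrow(peaks)) mean(n_hits > 0) else NA_real_)
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else ps_stop("genome must be a FASTA path, DNAStringSet or named character vector")
}

#' Write motif hits as BED6
#'
#' One line per hit with the matched text as name and the strand as
#' found; coordinates on the forward strand.
#'
#' @param hits data.frame from [scan_consensus()] (optionally with a
#'   `chrom` column; defaults to `"seq"`).
#' @param path output path.
#' @export
write_motif_hits <- function(hits, path) {
  con <- ps_connection(path, "w")
  on.exit(close(con))
  chrom <- if ("chrom" %in% names(hits)) hits$chrom else
    rep("seq", nrow(hits))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, hits$start,
                     hits$start + nchar(hits$matched), hits$matched,
                     hits$strand), con)
  invisible(path)
}
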