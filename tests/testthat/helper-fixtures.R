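# fixture builders and independent brute-force oracles used across tests

peak_df <- function(chrom, start, end, name = NULL, score = 0,
                    strand = ".", summit = NA_integer_) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end),
             name = if (is.null(name)) sprintf("p%03d", seq_len(n)) else name,
             score = rep_len(score, n), strand = rep_len(strand, n),
             summit = rep_len(as.integer(summit), n),
             stringsAsFactors = FALSE)
}

gene_df <- function(chrom, start, end, strand, gene_id = NULL,
                    biotype = "protein_coding", exon_starts = NULL,
                    exon_ends = NULL) {
  n <- length(start)
  g <- data.frame(
    gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n)) else gene_id,
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), strand = rep_len(strand, n),
    biotype = rep_len(biotype, n),
    exon_starts = if (is.null(exon_starts)) as.character(start) else exon_starts,
    exon_ends = if (is.null(exon_ends)) as.character(end) else exon_ends,
    stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g
}

# brute-force region classifier: per-peak loop over every gene, no
# vectorization or interval indexes; mirrors only the written rules
oracle_classify <- function(peaks, genes, upstream = 3000,
                            downstream = 300) {
  pts <- ifelse(!is.na(peaks$summit), peaks$summit,
                floor((peaks$start + peaks$end) / 2))
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- pts[i]
    prom <- intra <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- if (genes$strand[j] == "+") p - genes$tss[j] else genes$tss[j] - p
      if (d >= -upstream && d < 0) prom <- TRUE
      if (p >= genes$start[j] && p < genes$end[j]) intra <- TRUE
      dt <- if (genes$strand[j] == "+") p - genes$tes[j] else genes$tes[j] - p
      if (dt >= 1 && dt <= downstream) intra <- TRUE
    }
    if (prom) "promoter" else if (intra) "intragenic" else "distal_intergenic"
  }, character(1))
}

# exhaustive hypergeometric upper tail by subset enumeration (N <= 12)
oracle_hyper_sf <- function(a, K, n, N) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= a)
}

# naive O(n*m) IUPAC scan of the plus strand only
oracle_scan_plus <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p); n <- length(s)
  out <- integer(0)
  if (n < m) return(out)
  for (i in 1:(n - m + 1)) {
    ok <- TRUE
    for (j in 1:m) if (!(s[i + j - 1] %in% sets[[p[j]]])) { ok <- FALSE; break }
    if (ok) out <- c(out, i - 1L)
  }
  out
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# reflect a genome: coordinate x -> L - x, flipping strands; used for
# strand-mirror symmetry checks
reflect_genes <- function(genes, L) {
  g <- genes
  g$start <- as.integer(L - genes$end)
  g$end <- as.integer(L - genes$start)
  g$strand <- ifelse(genes$strand == "+", "-", "+")
  es <- strsplit(genes$exon_starts, ","); ee <- strsplit(genes$exon_ends, ",")
  g$exon_starts <- vapply(seq_along(es), function(i)
    paste(rev(L - as.numeric(ee[[i]])), collapse = ","), character(1))
  g$exon_ends <- vapply(seq_along(es), function(i)
    paste(rev(L - as.numeric(es[[i]])), collapse = ","), character(1))
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g
}

reflect_peaks <- function(peaks, L) {
  p <- peaks
  p$start <- as.integer(L - peaks$end)
  p$end <- as.integer(L - peaks$start)
  # reflected point of x is L-1-x so the point stays inside the interval
  p$summit <- ifelse(is.na(peaks$summit), NA_integer_,
                     as.integer(L - 1 - peaks$summit))
  p
}

# random small genome + peaks for property tests
random_fixture <- function(seed, n_genes = 8, n_peaks = 40, L = 200000) {
  withr::with_seed(seed, {
    starts <- sort(sample(seq(5000, L - 20000, by = 1000), n_genes))
    len <- sample(2000:8000, n_genes, replace = TRUE)
    genes <- gene_df("chrA", starts, pmin(starts + len, L - 5000),
                     strand = sample(c("+", "-"), n_genes, TRUE),
                     biotype = sample(c("protein_coding", "pseudogene",
                                        "lncRNA"), n_genes, TRUE,
                                      prob = c(.7, .15, .15)))
    ps <- sort(sample(0:(L - 500), n_peaks))
    peaks <- peak_df("chrA", ps, ps + sample(100:500, n_peaks, TRUE))
    list(genes = genes, peaks = peaks, L = L)
  })
}
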