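# count read anchors in [starts, ends) windows on one chromosome; reads
# must be sorted (coverage_track guarantees it)
count_in_windows <- function(reads, starts, ends) {
  if (is.null(reads) || !length(reads))
    return(integer(length(starts)))
  findInterval(ends - 0.5, reads) - findInterval(starts - 0.5, reads)
}

#' RPKM signal at peaks
#'
#' Counts track read anchors within each peak's query window (the peak
#' span padded by `flank` bp on each side by default, or a fixed window
#' around the summit when `anchor = "summit"`) and normalizes to window
#' width and sequencing depth:
#' `rpkm = count / (window_kb) / (library_size / 1e6)`.
#'
#' @param peaks peak data.frame.
#' @param track [coverage_track()].
#' @param flank padding in bp on each side of the query window.
#' @param anchor `"span"` (peak padded by flank) or `"summit"`
#'   (summit +/- flank).
#' @param genome optional named chromosome lengths used to truncate
#'   windows at chromosome ends (widths are recomputed).
#' @return data.frame `name`, `track`, `count`, `width`, `rpkm`.
#' @export
rpkm_at_peaks <- function(peaks, track, flank = 1000,
                          anchor = c("span", "summit"), genome = NULL) {
  anchor <- match.arg(anchor)
  if (flank < 0) ps_stop("flank must be non-negative")
  if (track$library_size <= 0) ps_stop("library_size must be positive")
  if (anchor == "span") {
    ws <- peaks$start - flank
    we <- peaks$end + flank
  } else {
    ctr <- classification_point(peaks)
    ws <- ctr - flank
    we <- ctr + flank + 1
  }
  ws <- pmax(ws, 0)
  if (!is.null(genome)) {
    lim <- unname(genome[peaks$chrom])
    we <- pmin(we, lim)
  }
  cnt <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- peaks$chrom == ch
    cnt[i] <- count_in_windows(track$reads[[ch]], ws[i], we[i])
  }
  width <- we - ws
  data.frame(name = peaks$name, track = track$label, count = cnt,
             width = width,
             rpkm = cnt / (width / 1000) / (track$library_size / 1e6),
             stringsAsFactors = FALSE)
}

profile_row <- function(reads, breaks, lib) {
  cnt <- diff(findInterval(breaks - 0.5, reads %||% numeric(0)))
  wid <- diff(breaks)
  cnt / (wid / 1000) / (lib / 1e6)
}

#' Peak-centered signal profile matrix
#'
#' One row per peak, centered on the summit (midpoint fallback), with
#' per-bin RPKM from `-half_window` to `+half_window`. Column names are
#' the bp offsets of the bin starts; the mean profile is the column-mean
#' vector.
#'
#' @inheritParams rpkm_at_peaks
#' @param half_window half-width of the profiled window in bp.
#' @param bin_width bin size in bp; must divide `half_window`.
#' @return numeric matrix (peaks x bins) with an attribute `bin_width`.
#' @export
peak_centered_profile <- function(peaks, track, half_window = 2000,
                                  bin_width = 50) {
  if (half_window %% bin_width != 0)
    ps_stop("half_window must be a multiple of bin_width")
  nb <- 2 * half_window / bin_width
  ctr <- classification_point(peaks)
  offs <- seq(-half_window, half_window, by = bin_width)
  mat <- matrix(0, nrow(peaks), nb,
                dimnames = list(peaks$name, offs[-length(offs)]))
  for (k in seq_len(nrow(peaks))) {
    mat[k, ] <- profile_row(track$reads[[peaks$chrom[k]]], ctr[k] + offs,
                            track$library_size)
  }
  attr(mat, "bin_width") <- bin_width
  mat
}

#' Scaled TSS-to-TES metagene profile matrix
#'
#' One row per gene. The gene body is linearly rescaled to `body_bins`
#' bins; `flank` bp on the 5' and 3' sides are profiled at fixed
#' resolution (`flank_bins` bins each). Minus-strand rows are reversed so
#' every row reads TSS to TES left to right. Genes shorter than
#' `body_bins` bp are skipped; the number skipped is recorded in the
#' `n_skipped` attribute (with a warning).
#'
#' @param genes gene-model data.frame.
#' @param track [coverage_track()].
#' @param flank flank size in bp.
#' @param flank_bins,body_bins bin counts for each flank and the body.
#' @return numeric matrix (genes x (2*flank_bins + body_bins)).
#' @export
metagene_profile <- function(genes, track, flank = 3000, flank_bins = 100,
                             body_bins = 100) {
  keep <- (genes$end - genes$start) >= body_bins
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " gene(s) shorter than body_bins bp skipped")
  g <- genes[keep, , drop = FALSE]
  nb <- 2 * flank_bins + body_bins
  mat <- matrix(0, nrow(g), nb, dimnames = list(g$gene_id, NULL))
  fb <- seq(0, flank, length.out = flank_bins + 1)
  for (k in seq_len(nrow(g))) {
    body <- seq(g$start[k], g$end[k], length.out = body_bins + 1)
    breaks <- c(g$start[k] - flank + fb[-(flank_bins + 1)], body,
                g$end[k] + fb[-1])
    row <- profile_row(track$reads[[g$chrom[k]]], breaks,
                       track$library_size)
    if (g$strand[k] == "-") row <- rev(row)
    mat[k, ] <- row
  }
  colnames(mat) <- c(paste0("up", rev(seq_len(flank_bins))),
                     paste0("body", seq_len(body_bins)),
                     paste0("down", seq_len(flank_bins)))
  attr(mat, "n_skipped") <- n_skipped
  mat
}

#' Per-stratum enrichment summary
#'
#' Summarizes per-peak RPKM values by stratum label (n, median, mean,
#' IQR). Empty strata are dropped with a warning.
#'
#' @param signals data.frame from [rpkm_at_peaks()].
#' @param strata character vector of labels, one per signal row, or a
#'   named vector mapping peak name to label.
#' @return data.frame with one row per stratum.
#' @export
stratified_enrichment <- function(signals, strata) {
  if (!is.null(names(strata))) strata <- unname(strata[signals$name])
  if (length(strata) != nrow(signals))
    ps_stop("every peak must carry a stratum label")
  if (anyNA(strata)) ps_stop("every peak must carry a stratum label")
  labs <- unique(strata)
  res <- lapply(labs, function(l) {
    v <- signals$rpkm[strata == l]
    data.frame(stratum = l, n = length(v), median = stats::median(v),
               mean = mean(v), iqr = stats::IQR(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  empty <- out$n == 0
  if (any(empty)) {
    warning("dropping empty strata: ", paste(out$stratum[empty],
                                             collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Write a profile matrix as TSV
#' @param mat profile matrix.
#' @param path output path.
#' @export
write_profile <- function(mat, path) {
  con <- ps_connection(path, "w")
  on.exit(close(con))
  utils::write.table(data.frame(row = rownames(mat), mat,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
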