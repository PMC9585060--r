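#' Significance stars for a p-value
#'
#' Encodes the conventional boxplot-legend cutpoints:
#' `****` p <= 1e-4, `***` p <= 1e-3, `**` p <= 0.01, `*` p < 0.05,
#' `ns` p >= 0.05. Note the mixed strict/non-strict operators: exactly
#' 0.05 is `ns`, exactly 0.01 is `**`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Pairwise group comparisons of per-peak signal
#'
#' Runs the two-sided Mann-Whitney test for each requested pair of
#' strata and attaches significance stars. P-values are reported
#' unadjusted (one test per printed comparison); set `bonferroni = TRUE`
#' to multiply by the number of pairs.
#'
#' @param signals data.frame from [rpkm_at_peaks()].
#' @param strata stratum label per signal row (or named map, see
#'   [stratified_enrichment()]).
#' @param pairs list of length-2 character vectors of stratum labels;
#'   defaults to all pairs.
#' @param bonferroni apply Bonferroni correction across the panel.
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `median1`,
#'   `median2`, `U`, `p_value`, `stars`, `method`.
#' @export
compare_groups <- function(signals, strata, pairs = NULL,
                           bonferroni = FALSE) {
  if (!is.null(names(strata))) strata <- unname(strata[signals$name])
  labs <- unique(strata)
  if (is.null(pairs))
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    x <- signals$rpkm[strata == pr[1]]
    y <- signals$rpkm[strata == pr[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning("skipping pair ", pr[1], " vs ", pr[2],
              ": stratum with n < 2")
      next
    }
    tst <- mann_whitney(x, y)
    p <- if (bonferroni) min(1, tst$p_value * length(pairs)) else
      tst$p_value
    rows[[length(rows) + 1]] <- data.frame(
      group1 = pr[1], group2 = pr[2], n1 = tst$n1, n2 = tst$n2,
      median1 = stats::median(x), median2 = stats::median(y),
      U = tst$statistic, p_value = p, stars = p_stars(p),
      method = tst$method, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), median1 = numeric(),
                      median2 = numeric(), U = numeric(),
                      p_value = numeric(), stars = character(),
                      method = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Run the full peak-integration pipeline
#'
#' Stages run in order: annotate, colocalization (one block per
#' companion peak set), signal quantification (one block per coverage
#' track, stratified by region class and DE direction), direct-target
#' calling, and motif scanning. A failure in one companion track is
#' recorded in its block and does not abort the others.
#'
#' The configuration is a list (or YAML file path) with either a
#' `simulate` block (arguments to [synthetic_config()]) or an `inputs`
#' block with file paths: `peaks` (+ `peaks_format`), `genes`
#' (+ `genes_format`), `chrom_sizes`, optional `companion_peaks` (named
#' list of BED paths), `tracks` (named list of read-anchor BED paths),
#' `de`, `genome_fasta`. An optional `params` block overrides thresholds
#' (`upstream`, `downstream`, `flank`, `lfc`, `fdr`, `min_count`,
#' `bin_width`, `motif`).
#'
#' @param config list or YAML path.
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  prm <- config$params %||% list()
  upstream <- prm$upstream %||% 3000
  downstream <- prm$downstream %||% 300
  flank <- prm$flank %||% 1000
  lfc <- prm$lfc %||% 0.5
  fdr <- prm$fdr %||% 0.05
  min_count <- prm$min_count %||% 25
  motif <- prm$motif %||% "GGTTAATNATTAAC"

  if (!is.null(config$simulate)) {
    sim <- simulate_study(do.call(synthetic_config, config$simulate))
    peaks <- sim$peaks; genes <- sim$genes
    genome <- sim$chrom_lengths
    companions <- list(companion = sim$companion_peaks)
    tracks <- list(ATAC = sim$coverage)
    de <- sim$de
    gseq <- sim$genome_seq
    seed <- sim$config$seed
  } else {
    inp <- config$inputs
    if (is.null(inp)) ps_stop("config needs a 'simulate' or 'inputs' block")
    paths <- c(inp$peaks, inp$genes, inp$chrom_sizes,
               unlist(inp$companion_peaks), unlist(inp$tracks), inp$de,
               inp$genome_fasta)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      ps_stop("missing input file(s): ", paste(missing, collapse = ", "))
    peaks <- read_peaks(inp$peaks, inp$peaks_format %||% "narrowPeak")
    genes <- read_gene_models(inp$genes, inp$genes_format %||% "tsv")
    genome <- read_chrom_sizes(inp$chrom_sizes)
    companions <- lapply(inp$companion_peaks %||% list(), read_peaks,
                         format = "bed6")
    tracks <- list()
    for (nm in names(inp$tracks %||% list()))
      tracks[[nm]] <- read_coverage(inp$tracks[[nm]], "readbed",
                                    label = nm)
    de <- if (!is.null(inp$de)) read_de_table(inp$de) else NULL
    gseq <- if (!is.null(inp$genome_fasta)) inp$genome_fasta else NULL
    seed <- config$seed %||% NA
  }

  ann <- classify_peaks(peaks, genes, upstream = upstream,
                        downstream = downstream)
  report <- list(
    provenance = list(tool = "peakscape",
                      version = as.character(utils::packageVersion("peakscape")),
                      seed = seed, config_hash = config_hash(config),
                      thresholds = list(upstream = upstream,
                                        downstream = downstream,
                                        flank = flank, lfc = lfc, fdr = fdr,
                                        min_count = min_count)),
    n_peaks = nrow(peaks),
    region_summary = summarize_regions(ann))

  if (length(companions)) {
    report$colocalization <- lapply(companions, function(B) {
      tryCatch(unclass(coloc_test(peaks, B, genome,
                                  bin_width = prm$bin_width)),
               error = function(e) list(error = conditionMessage(e)))
    })
  }

  calls <- NULL
  if (!is.null(de)) {
    tc <- call_direct_targets(de, ann, lfc_threshold = lfc,
                              fdr_threshold = fdr,
                              min_mean_count = min_count)
    calls <- tc$calls
    report$targets <- tc$summary
  }

  if (length(tracks)) {
    report$signal <- lapply(tracks, function(tr) {
      tryCatch({
        sig <- rpkm_at_peaks(peaks, tr, flank = flank, genome = genome)
        blk <- list(by_region = stratified_enrichment(sig, ann$region_class))
        if (!is.null(calls)) {
          dirmap <- stats::setNames(calls$direction, calls$gene_id)
          lab <- ifelse(is.na(ann$assigned_gene), "unassigned",
                        unname(dirmap[ann$assigned_gene]))
          lab[is.na(lab)] <- "unassigned"
          keep <- lab %in% c("activated", "repressed")
          if (sum(keep) >= 4 && length(unique(lab[keep])) == 2) {
            blk$by_direction <- stratified_enrichment(sig[keep, ], lab[keep])
            blk$activated_vs_repressed <-
              compare_groups(sig[keep, ], lab[keep],
                             pairs = list(c("activated", "repressed")))
          }
        }
        blk
      }, error = function(e) list(error = conditionMessage(e)))
    })
  }

  if (!is.null(gseq)) {
    report$motif <- tryCatch({
      mres <- peaks_with_motif(peaks, gseq, pattern = motif)
      list(pattern = motif,
           fraction_with_motif = mres$fraction_with_motif,
           n_with_motif = sum(mres$per_peak$n_hits > 0))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  structure(report, class = "pipeline_report",
            annotations = ann, calls = calls)
}

# order-insensitive content hash of the config (djb2 over serialized JSON)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  h <- 5381
  for (ci in utf8ToInt(as.character(s))) h <- (h * 33 + ci) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("peakscape pipeline report\n")
  cat(sprintf("  peaks: %d\n", x$n_peaks))
  rs <- x$region_summary
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s %.1f%%", rs$region_class, rs$pct),
                    collapse = ", ")))
  for (nm in names(x$colocalization)) {
    b <- x$colocalization[[nm]]
    if (!is.null(b$error)) cat(sprintf("  coloc[%s]: ERROR %s\n", nm, b$error))
    else cat(sprintf("  coloc[%s]: %.1f%% overlap, OR %.2f, p %.3g\n", nm,
                     100 * b$fraction_A, b$odds_ratio, b$p_value))
  }
  if (!is.null(x$targets))
    cat(sprintf("  targets: %d/%d direct activated (%.1f%%), %d/%d direct repressed (%.1f%%)\n",
                x$targets$n_direct_activated, x$targets$n_activated,
                x$targets$pct_direct_activated,
                x$targets$n_direct_repressed, x$targets$n_repressed,
                x$targets$pct_direct_repressed))
  if (!is.null(x$motif) && is.null(x$motif$error))
    cat(sprintf("  motif: %.1f%% of peaks carry %s\n",
                100 * x$motif$fraction_with_motif, x$motif$pattern))
  invisible(x)
}

#' Write a pipeline report as JSON
#' @param report [run_pipeline()] output.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
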