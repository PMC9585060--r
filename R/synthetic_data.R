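#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic-data generators with the
#' defaults used throughout the test surface: a desk-scale two-chromosome
#' genome, a gene complement with a protein-coding-dominated biotype mix,
#' a peak set whose planted region composition matches the
#' promoter/intragenic/distal split observed for the factor (26/37/37%),
#' Poisson coverage with controllable fold enrichment, and a DE table
#' with planted direct targets. A single integer seed drives a named
#' substream per generator, so outputs are byte-reproducible and adding
#' one generator never perturbs another.
#'
#' @param seed master RNG seed.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_genes number of genes.
#' @param gene_length_range min/max gene length (bp).
#' @param biotype_mix named fractions over
#'   protein_coding/lncRNA/miRNA/pseudogene/other; must sum to 1.
#' @param n_peaks number of peaks in the primary set.
#' @param region_mix named fractions (promoter, intragenic, distal)
#'   governing where peak summits are planted; must sum to 1.
#' @param peak_width_meanlog,peak_width_sdlog lognormal peak widths
#'   (around 300 bp by default).
#' @param coloc_odds_ratio planted bin-level odds ratio for the companion
#'   peak set.
#' @param coloc_background fraction of background bins hit by the
#'   companion set.
#' @param enrichment_fold coverage fold change inside signal-peak windows
#'   relative to background (1 = none).
#' @param enrichment_flank bp of flank around signal peaks sharing the
#'   planted enrichment (matches the 1-kb RPKM query window).
#' @param background_rate background read density (reads/bp).
#' @param library_size optional library-size override for generated
#'   tracks.
#' @param n_direct_activated,n_direct_repressed planted direct targets.
#' @param lfc_effect minimum |log2fc| of planted targets.
#' @param fdr_noise fraction of null genes given a spurious significant
#'   call.
#' @param frac_low_expressed fraction of genes below the expression
#'   filter.
#' @param motif_fraction fraction of peaks with a planted consensus
#'   instance at the summit.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    n_genes = 200,
    gene_length_range = c(2000, 8000),
    biotype_mix = c(protein_coding = 0.70, lncRNA = 0.10, miRNA = 0.05,
                    pseudogene = 0.10, other = 0.05),
    n_peaks = 500,
    region_mix = c(promoter = 0.26, intragenic = 0.37, distal = 0.37),
    peak_width_meanlog = log(300), peak_width_sdlog = 0.3,
    coloc_odds_ratio = 1, coloc_background = 0.05,
    enrichment_fold = 1, enrichment_flank = 1000,
    background_rate = 0.02, library_size = NULL,
    n_direct_activated = 50, n_direct_repressed = 50,
    lfc_effect = 1, fdr_noise = 0.02, frac_low_expressed = 0.05,
    motif_fraction = 0.3) {
  cfg <- as.list(environment())
  if (abs(sum(biotype_mix) - 1) > 1e-8) ps_stop("biotype_mix must sum to 1")
  if (abs(sum(region_mix) - 1) > 1e-8) ps_stop("region_mix must sum to 1")
  if (any(biotype_mix < 0) || any(region_mix < 0))
    ps_stop("mix fractions must be non-negative")
  if (coloc_odds_ratio < 0) ps_stop("coloc_odds_ratio must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# minimum spacing between genes: promoter window + downstream window +
# margin, so planted region classes never collide across neighbors
GENE_GAP <- 3400

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes with at least 3.4 kb spacing (so promoter
#' and downstream windows are unambiguous), Bernoulli(0.5) strands, 1-5
#' exons each, and biotypes drawn from the configured mix.
#'
#' @param config [synthetic_config()].
#' @return gene-model data.frame (see [read_gene_models()]).
#' @export
generate_annotation <- function(config) {
  with_seed(derive_seed(config$seed, "annotation"), {
    L <- config$chrom_lengths
    n <- config$n_genes
    # genes per chromosome, proportional to length (largest remainder)
    share <- n * L / sum(L)
    k <- floor(share)
    rem <- n - sum(k)
    if (rem > 0) {
      o <- order(share - k, decreasing = TRUE)
      k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
    }
    rows <- list()
    for (ci in seq_along(L)) {
      kk <- k[ci]
      if (kk == 0) next
      len <- round(stats::runif(kk, config$gene_length_range[1],
                                config$gene_length_range[2]))
      slack <- L[ci] - sum(len) - (kk + 1) * GENE_GAP
      if (slack < 0)
        ps_stop("cannot pack ", kk, " genes into ", names(L)[ci],
                "; increase the genome or reduce n_genes")
      cuts <- sort(stats::runif(kk))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      gaps <- GENE_GAP + extra           # kk+1 gaps; the last stays open
      starts <- cumsum(gaps[seq_len(kk)]) + cumsum(c(0, len[-kk]))
      rows[[ci]] <- data.frame(
        chrom = names(L)[ci], start = starts, end = starts + len,
        strand = ifelse(stats::runif(kk) < 0.5, "+", "-"),
        biotype = sample(names(config$biotype_mix), kk, replace = TRUE,
                         prob = config$biotype_mix),
        stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
    g$gene_id <- sprintf("gene%04d", seq_len(nrow(g)))
    # exon structure: first exon starts at gene start, last ends at end
    g$exon_starts <- g$exon_ends <- ""
    for (i in seq_len(nrow(g))) {
      len <- g$end[i] - g$start[i]
      k_ex <- sample(1:5, 1)
      if (len < 2 * k_ex) k_ex <- 1L
      if (k_ex == 1) {
        es <- g$start[i]; ee <- g$end[i]
      } else {
        cuts <- sort(sample(seq_len(len - 1), 2 * (k_ex - 1)))
        bounds <- c(0, cuts, len) + g$start[i]
        es <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ee <- bounds[seq(2, length(bounds), by = 2)]
      }
      g$exon_starts[i] <- paste(es, collapse = ",")
      g$exon_ends[i] <- paste(ee, collapse = ",")
    }
    finish_genes(g)
  })
}

#' Generate a synthetic peak set with planted region composition
#'
#' Each peak's summit is placed inside a region sampled from
#' `region_mix`: the strand-aware 3 kb promoter window of a random gene,
#' a random gene body, or the distal intergenic complement. Widths are
#' lognormal around 300 bp; summits are recorded, so classification by
#' [classify_peaks()] recovers the planted composition.
#'
#' @param genes gene-model data.frame from [generate_annotation()].
#' @param config [synthetic_config()].
#' @return peak data.frame.
#' @export
generate_peaks <- function(genes, config) {
  n <- config$n_peaks
  if (n == 0) return(empty_peaks())
  with_seed(derive_seed(config$seed, "peaks"), {
    L <- config$chrom_lengths
    cls <- sample(c("promoter", "intragenic", "distal"), n, replace = TRUE,
                  prob = config$region_mix[c("promoter", "intragenic",
                                             "distal")])
    # distal complement: everything outside promoter/body/downstream
    blocked <- lapply(names(L), function(ch) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      if (!nrow(g)) return(cbind(numeric(0), numeric(0)))
      lo <- ifelse(g$strand == "+", g$start - 3000, g$start - 300)
      hi <- ifelse(g$strand == "+", g$end + 300, g$end + 3000)
      cbind(pmax(0, lo), pmin(L[[ch]], hi))
    })
    names(blocked) <- names(L)
    free <- lapply(names(L), function(ch) {
      b <- blocked[[ch]]
      if (!nrow(b)) return(cbind(0, L[[ch]]))
      # merge overlapping blocked windows (opposing-strand flanks of
      # neighboring genes can collide), then complement
      o <- order(b[, 1])
      b <- b[o, , drop = FALSE]
      ms <- b[1, 1]; me <- b[1, 2]; merged <- NULL
      for (i in seq_len(nrow(b))[-1]) {
        if (b[i, 1] <= me) me <- max(me, b[i, 2])
        else { merged <- rbind(merged, c(ms, me)); ms <- b[i, 1]; me <- b[i, 2] }
      }
      merged <- rbind(merged, c(ms, me))
      edges <- c(0, as.vector(t(merged)), L[[ch]])
      m <- matrix(edges, ncol = 2, byrow = TRUE)
      m[m[, 2] - m[, 1] > 2, , drop = FALSE] # keep usable gaps
    })
    names(free) <- names(L)
    point <- numeric(n); chrom <- character(n)
    gi_prom <- sample(nrow(genes), n, replace = TRUE)
    for (i in seq_len(n)) {
      if (cls[i] == "promoter") {
        g <- genes[gi_prom[i], ]
        off <- floor(stats::runif(1, 1, 3000 + 1)) # 1..3000 bp upstream
        point[i] <- if (g$strand == "+") g$tss - off else g$tss + off
        chrom[i] <- g$chrom
      } else if (cls[i] == "intragenic") {
        g <- genes[gi_prom[i], ]
        point[i] <- floor(stats::runif(1, g$start, g$end))
        chrom[i] <- g$chrom
      } else {
        lens <- vapply(free, function(m) sum(m[, 2] - m[, 1]), numeric(1))
        if (sum(lens) <= 0) ps_stop("no intergenic space left for distal peaks")
        ch <- sample(names(L), 1, prob = lens)
        m <- free[[ch]]
        seg <- sample(nrow(m), 1, prob = m[, 2] - m[, 1])
        point[i] <- floor(stats::runif(1, m[seg, 1] + 1, m[seg, 2] - 1))
        chrom[i] <- ch
      }
    }
    w <- pmax(50, round(stats::rlnorm(n, config$peak_width_meanlog,
                                      config$peak_width_sdlog)))
    start <- pmax(0, round(point - w / 2))
    end <- pmin(unname(L[chrom]), start + w)
    start <- pmin(start, point)        # keep summit inside after clamping
    end <- pmax(end, point + 1)
    df <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(end),
                     name = sprintf("peak%05d", seq_len(n)),
                     score = round(stats::runif(n, 10, 1000)),
                     strand = ".", summit = as.integer(point),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), ]
  })
}

#' Generate a companion peak set with planted bin-level odds ratio
#'
#' Tiles the genome into bins of the median A peak width (the same
#' default [binned_contingency()] uses). Bins hit by A receive a
#' companion peak with probability `p1`, other bins with probability
#' `p0 = coloc_background`, where `p1/(1-p1) = theta * p0/(1-p0)`. Each
#' companion peak lies entirely inside its bin, so the planted bin-level
#' odds ratio equals `theta` in expectation.
#'
#' @param A peak data.frame (the primary set).
#' @param genome named chromosome lengths.
#' @param theta planted odds ratio (>= 0).
#' @param config [synthetic_config()].
#' @return peak data.frame.
#' @export
generate_colocalized_peaks <- function(A, genome, theta = NULL,
                                       config = synthetic_config()) {
  if (is.null(theta)) theta <- config$coloc_odds_ratio
  if (theta < 0) ps_stop("theta must be >= 0")
  p0 <- config$coloc_background
  odds1 <- theta * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  bw <- max(1, round(stats::median(A$end - A$start)))
  with_seed(derive_seed(config$seed, "coloc"), {
    rows <- list()
    for (ch in names(genome)) {
      nb <- as.integer(ceiling(genome[[ch]] / bw))
      ai <- with(A[A$chrom == ch, , drop = FALSE],
                 hit_bins(start, end, bw, nb))
      p <- rep(p0, nb)
      p[ai + 1] <- p1
      hit <- which(stats::runif(nb) < p) - 1
      if (!length(hit)) next
      bin_start <- hit * bw
      bin_end <- pmin(genome[[ch]], bin_start + bw)
      wb <- pmin(bin_end - bin_start,
                 pmax(20, round(stats::rlnorm(length(hit),
                                              config$peak_width_meanlog,
                                              config$peak_width_sdlog))))
      s <- bin_start + floor(stats::runif(length(hit)) *
                               (bin_end - bin_start - wb + 1))
      rows[[ch]] <- data.frame(chrom = ch, start = as.integer(s),
                               end = as.integer(s + wb),
                               stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty_peaks())
    df <- do.call(rbind, rows)
    df$name <- sprintf("cpeak%05d", seq_len(nrow(df)))
    df$score <- 0; df$strand <- "."; df$summit <- NA_integer_
    rownames(df) <- NULL
    df[, c("chrom", "start", "end", "name", "score", "strand", "summit")]
  })
}

#' Generate a coverage track with planted enrichment
#'
#' Poisson background at `background_rate` reads/bp across the genome;
#' inside the windows of `signal_peaks` (peak span padded by
#' `enrichment_flank`) the total rate is `enrichment_fold` times the
#' background, i.e. an extra Poisson component at
#' `(fold - 1) * background_rate`.
#'
#' @param signal_peaks peak data.frame receiving the planted enrichment
#'   (may be empty).
#' @param config [synthetic_config()].
#' @param label track label.
#' @param stream RNG substream name (vary it to draw independent tracks).
#' @return [coverage_track()].
#' @export
generate_coverage <- function(signal_peaks, config, label = "track",
                              stream = paste0("coverage:", label)) {
  rate <- config$background_rate
  fold <- config$enrichment_fold
  if (fold < 1) ps_stop("enrichment_fold must be >= 1")
  with_seed(derive_seed(config$seed, stream), {
    reads <- list()
    for (ch in names(config$chrom_lengths)) {
      len <- config$chrom_lengths[[ch]]
      n_bg <- stats::rpois(1, rate * len)
      pos <- if (n_bg > 0) floor(stats::runif(n_bg) * len) else numeric(0)
      sp <- signal_peaks[signal_peaks$chrom == ch, , drop = FALSE]
      if (nrow(sp) && fold > 1 && rate > 0) {
        ws <- pmax(0, sp$start - config$enrichment_flank)
        we <- pmin(len, sp$end + config$enrichment_flank)
        n_sig <- stats::rpois(nrow(sp), (fold - 1) * rate * (we - ws))
        extra <- unlist(mapply(function(s, e, k)
          if (k > 0) floor(stats::runif(k, s, e)) else numeric(0),
          ws, we, n_sig, SIMPLIFY = FALSE))
        pos <- c(pos, extra)
      }
      reads[[ch]] <- sort(pos)
    }
    lib <- config$library_size
    if (sum(lengths(reads)) == 0 && is.null(lib)) lib <- 1
    coverage_track(reads, library_size = lib, label = label)
  })
}

#' Generate a DE table with planted direct targets
#'
#' Planted activated genes draw `log2fc <= -lfc_effect` with
#' `fdr < 0.05`; planted repressed genes mirror them. Null genes draw
#' small fold changes and `fdr >= 0.05` except a `fdr_noise` fraction of
#' spurious significant calls; a `frac_low_expressed` fraction falls
#' below the 25-count expression filter. Mean counts are >= 25 for all
#' non-filtered genes.
#'
#' @param genes gene-model data.frame.
#' @param bound_genes gene ids with at least one assigned peak; planted
#'   direct targets are drawn from these.
#' @param config [synthetic_config()].
#' @return list with `de` (DE data.frame) and `truth` (per-gene planted
#'   status: direct_activated / direct_repressed / spurious /
#'   low_expressed / null).
#' @export
generate_de_table <- function(genes, bound_genes, config) {
  n_act <- config$n_direct_activated
  n_rep <- config$n_direct_repressed
  if (n_act + n_rep > length(bound_genes))
    ps_stop("more planted direct targets (", n_act + n_rep,
            ") than bound genes (", length(bound_genes), ")")
  if (!all(bound_genes %in% genes$gene_id))
    ps_stop("bound_genes must come from the supplied gene models")
  with_seed(derive_seed(config$seed, "de"), {
    ids <- genes$gene_id
    n <- length(ids)
    planted <- sample(bound_genes, n_act + n_rep)
    act <- planted[seq_len(n_act)]
    rep_ <- setdiff(planted, act)
    status <- stats::setNames(rep("null", n), ids)
    status[act] <- "direct_activated"
    status[rep_] <- "direct_repressed"
    rest <- ids[status == "null"]
    n_low <- round(config$frac_low_expressed * n)
    low <- utils::head(sample(rest), n_low)
    status[low] <- "low_expressed"
    rest <- ids[status == "null"]
    n_spur <- round(config$fdr_noise * length(rest))
    spur <- utils::head(sample(rest), n_spur)
    status[spur] <- "spurious"

    lfc <- stats::rnorm(n, 0, 0.15)
    fdr <- stats::runif(n, 0.05, 1)
    i_act <- ids %in% act
    i_rep <- ids %in% rep_
    i_spur <- ids %in% spur
    lfc[i_act] <- -(config$lfc_effect + abs(stats::rnorm(sum(i_act), 0, 0.3)))
    lfc[i_rep] <- config$lfc_effect + abs(stats::rnorm(sum(i_rep), 0, 0.3))
    lfc[i_spur] <- sample(c(-1, 1), sum(i_spur), replace = TRUE) *
      (0.5 + abs(stats::rnorm(sum(i_spur), 0, 0.3)))
    sig <- i_act | i_rep | i_spur
    fdr[sig] <- stats::runif(sum(sig), 0, 0.049)

    base <- pmax(26, round(stats::rlnorm(n, log(200), 1)))
    i_low <- ids %in% low
    base[i_low] <- round(stats::runif(sum(i_low), 1, 24))
    ctrl <- base
    mut <- pmax(0, round(base * 2^lfc))
    mut[i_low] <- pmin(24, mut[i_low])
    de <- data.frame(gene_id = ids, log2fc = round(lfc, 4),
                     fdr = signif(fdr, 4), mean_count_control = ctrl,
                     mean_count_mutant = mut, stringsAsFactors = FALSE)
    list(de = validate_de_table(de),
         truth = data.frame(gene_id = ids, status = unname(status[ids]),
                            stringsAsFactors = FALSE))
  })
}

#' Generate genome sequence with planted consensus instances
#'
#' Uniform-random ACGT sequence per chromosome, with the IUPAC consensus
#' (ambiguity codes resolved randomly) written at the summit of a
#' `motif_fraction` sample of peaks.
#'
#' @param peaks peak data.frame.
#' @param config [synthetic_config()].
#' @param pattern IUPAC consensus to plant.
#' @return named character vector of chromosome sequences, plus an
#'   attribute `planted` naming the peaks carrying an instance.
#' @export
generate_genome_sequence <- function(peaks, config,
                                     pattern = "GGTTAATNATTAAC") {
  with_seed(derive_seed(config$seed, "sequence"), {
    seqs <- lapply(config$chrom_lengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
    chosen <- if (nrow(peaks))
      sort(sample(nrow(peaks), round(config$motif_fraction * nrow(peaks))))
    else integer(0)
    pc <- strsplit(pattern, "")[[1]]
    for (k in chosen) {
      inst <- paste(vapply(pc, function(cd) {
        s <- setdiff(IUPAC_SETS[[cd]], "N")
        if (length(s) == 1) s else sample(s, 1)
      }, character(1)), collapse = "")
      ch <- peaks$chrom[k]
      # centered on the summit so the instance stays inside the peak span
      at <- peaks$summit[k] - (nchar(pattern) %/% 2)
      at <- max(0, min(at, nchar(seqs[[ch]]) - nchar(pattern)))
      substr(seqs[[ch]], at + 1, at + nchar(pattern)) <- inst
    }
    structure(unlist(seqs), planted = peaks$name[chosen])
  })
}

#' Run the full synthetic study
#'
#' Generates, in order: gene models, the primary peak set, annotations,
#' a companion peak set with the planted colocalization odds ratio, a
#' coverage track enriched at peaks of planted activated genes, a DE
#' table with planted direct targets, and genome sequence with planted
#' motif instances.
#'
#' @param config [synthetic_config()].
#' @return list with components `config`, `genes`, `peaks`,
#'   `annotations`, `companion_peaks`, `coverage`, `de`, `truth`,
#'   `genome_seq`, `chrom_lengths`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  genes <- generate_annotation(config)
  peaks <- generate_peaks(genes, config)
  ann <- classify_peaks(peaks, genes)
  bound <- unique(stats::na.omit(ann$assigned_gene))
  det <- generate_de_table(genes, bound, config)
  act <- det$truth$gene_id[det$truth$status == "direct_activated"]
  signal_peaks <- peaks[peaks$name %in%
                          ann$name[ann$assigned_gene %in% act], ,
                        drop = FALSE]
  cov <- generate_coverage(signal_peaks, config, label = "ATAC")
  comp <- generate_colocalized_peaks(peaks, config$chrom_lengths,
                                     config$coloc_odds_ratio, config)
  gseq <- generate_genome_sequence(peaks, config)
  list(config = config, genes = genes, peaks = peaks, annotations = ann,
       companion_peaks = comp, coverage = cov, de = det$de,
       truth = det$truth, genome_seq = gseq,
       chrom_lengths = config$chrom_lengths)
}

#' Write a synthetic study to disk
#'
#' Emits the exact formats the readers consume: `peaks.narrowPeak`,
#' `companion_peaks.bed`, `genes.tsv`, `coverage.bed` (read anchors),
#' `de.tsv`, `genome.fa`, `chrom.sizes`, and `truth.json` with the
#' planted parameters.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peaks(sim$peaks, file.path(dir, "peaks.narrowPeak"), "narrowPeak")
  write_peaks(sim$companion_peaks, file.path(dir, "companion_peaks.bed"),
              "bed6")
  write_gene_models(sim$genes, file.path(dir, "genes.tsv"), "tsv")
  write_coverage(sim$coverage, file.path(dir, "coverage.bed"))
  write_de_table(sim$de, file.path(dir, "de.tsv"))
  writeLines(unlist(lapply(names(sim$genome_seq), function(ch)
    c(paste0(">", ch), sim$genome_seq[[ch]]))),
    file.path(dir, "genome.fa"))
  writeLines(sprintf("%s\t%d", names(sim$chrom_lengths),
                     as.integer(sim$chrom_lengths)),
             file.path(dir, "chrom.sizes"))
  truth <- list(seed = sim$config$seed,
                region_mix = as.list(sim$config$region_mix),
                coloc_odds_ratio = sim$config$coloc_odds_ratio,
                enrichment_fold = sim$config$enrichment_fold,
                planted_activated =
                  sim$truth$gene_id[sim$truth$status == "direct_activated"],
                planted_repressed =
                  sim$truth$gene_id[sim$truth$status == "direct_repressed"],
                motif_peaks = attr(sim$genome_seq, "planted"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
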