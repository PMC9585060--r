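#' Classify peaks by genomic region and assign genes
#'
#' Each peak is reduced to a classification point (its summit when
#' present, otherwise the interval midpoint) and classified, with
#' precedence promoter > intragenic > distal intergenic:
#' \itemize{
#'   \item promoter: within the 3 kb (configurable) immediately upstream
#'     of any TSS, strand-aware;
#'   \item intragenic: inside any gene body (exons, introns, UTR proxies)
#'     or at most 300 bp (configurable) downstream of any TES;
#'   \item distal intergenic: anywhere else.
#' }
#' Peaks are assigned to the gene with the nearest TSS (among
#' promoter-window genes when the class is promoter, so the signed
#' distance of a promoter peak always lies in `[-upstream, 0)`). Ties are
#' broken by lexicographically smallest `gene_id`. When the nearest-TSS
#' gene is a pseudogene and the point falls inside the body of a
#' non-pseudogene gene, the peak is reassigned to that enclosing gene.
#'
#' @param peaks peak data.frame (see [read_peaks()]).
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param upstream promoter window size in bp upstream of the TSS.
#' @param downstream downstream window size in bp past the TES counted as
#'   intragenic.
#' @param max_tss_distance optional cap in bp on nearest-promoter
#'   assignment; peaks farther than this from every TSS get no gene.
#' @return data.frame with one row per peak: `name`, `chrom`, `start`,
#'   `end`, `point`, `region_class`, `subregion`, `assigned_gene`,
#'   `assigned_biotype`, `distance_to_tss` (signed bp, negative =
#'   upstream of the assigned TSS).
#' @export
classify_peaks <- function(peaks, genes, upstream = 3000, downstream = 300,
                           max_tss_distance = NULL) {
  pts <- classification_point(peaks)
  n <- nrow(peaks)
  out <- data.frame(
    name = peaks$name, chrom = peaks$chrom, start = peaks$start,
    end = peaks$end, point = pts,
    region_class = rep("distal_intergenic", n),
    subregion = rep("none", n),
    assigned_gene = rep(NA_character_, n),
    assigned_biotype = rep(NA_character_, n),
    distance_to_tss = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (n == 0 || nrow(genes) == 0) return(out)

  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    p <- pts[pi]
    plus <- g$strand == "+"
    # signed strand-aware distance to each TSS: negative = upstream
    d <- outer(p, g$tss, "-")
    d[, !plus] <- -d[, !plus, drop = FALSE]
    in_prom <- d >= -upstream & d < 0
    in_body <- outer(p, g$start, ">=") & outer(p, g$end, "<")
    # downstream window past the TES, strand-aware
    d_tes <- outer(p, g$tes, "-")
    d_tes[, !plus] <- -d_tes[, !plus, drop = FALSE]
    in_down <- d_tes >= 1 & d_tes <= downstream
    in_intra <- in_body | in_down

    cls <- ifelse(rowSums(in_prom) > 0, "promoter",
                  ifelse(rowSums(in_intra) > 0, "intragenic",
                         "distal_intergenic"))
    out$region_class[pi] <- cls

    absd <- abs(d)
    gid <- g$gene_id
    ord_rank <- rank(gid, ties.method = "first") # lexicographic tie-break
    for (k in seq_along(pi)) {
      cand <- if (cls[k] == "promoter") which(in_prom[k, ]) else
        seq_len(nrow(g))
      dk <- absd[k, cand]
      best <- cand[dk == min(dk)]
      j <- best[which.min(ord_rank[best])]
      # pseudogene-to-host reassignment: a point nearest a pseudogene TSS
      # but lying inside a non-pseudogene gene body belongs to the host
      # gene; promoter-class calls keep their promoter-window gene so the
      # promoter distance invariant holds
      if (cls[k] != "promoter" && g$biotype[j] == "pseudogene") {
        hosts <- which(in_body[k, ] & g$biotype != "pseudogene")
        if (length(hosts)) {
          dh <- absd[k, hosts]
          bh <- hosts[dh == min(dh)]
          j <- bh[which.min(ord_rank[bh])]
        }
      }
      if (!is.null(max_tss_distance) && absd[k, j] > max_tss_distance) next
      out$assigned_gene[pi[k]] <- gid[j]
      out$assigned_biotype[pi[k]] <- g$biotype[j]
      out$distance_to_tss[pi[k]] <- d[k, j]
      if (cls[k] == "intragenic")
        out$subregion[pi[k]] <- subregion_label(p[k], g, in_body[k, ],
                                                in_down[k, ], j, ord_rank)
    }
  }
  out
}

classification_point <- function(peaks) {
  ifelse(!is.na(peaks$summit), peaks$summit,
         floor((peaks$start + peaks$end) / 2))
}

# Describe where inside a gene an intragenic point falls. The containing
# gene is the assigned gene when it contains the point, otherwise the
# first containing gene; points only in a downstream window get
# "downstream<=300". First exon in transcription order proxies the 5'UTR
# when no CDS is available.
subregion_label <- function(p, g, body_row, down_row, assigned_j, ord_rank) {
  j <- if (body_row[assigned_j]) assigned_j else {
    inside <- which(body_row)
    if (!length(inside)) return("downstream<=300")
    inside[which.min(ord_rank[inside])]
  }
  es <- as.numeric(strsplit(g$exon_starts[j], ",")[[1]])
  ee <- as.numeric(strsplit(g$exon_ends[j], ",")[[1]])
  if (!length(es)) return("intron")
  hit <- which(p >= es & p < ee)
  if (!length(hit)) return("intron")
  first_exon <- if (g$strand[j] == "+") 1L else length(es)
  if (hit[1] == first_exon) "5UTR-proxy:first-exon" else "exon"
}

#' Nearest-promoter gene assignment
#'
#' Convenience wrapper over [classify_peaks()] returning just the
#' assigned gene per peak.
#'
#' @inheritParams classify_peaks
#' @return character vector of gene ids, `NA` where unassigned.
#' @export
assign_genes <- function(peaks, genes, max_tss_distance = NULL) {
  classify_peaks(peaks, genes, max_tss_distance = max_tss_distance)$assigned_gene
}

#' Summarize region classification
#'
#' Counts and percentages of peaks per region class, optionally
#' stratified by the biotype of the assigned gene.
#'
#' @param annotations output of [classify_peaks()].
#' @param stratify_by `NULL` or `"biotype"`.
#' @return data.frame of counts and percentages; counts sum to the input
#'   size.
#' @export
summarize_regions <- function(annotations, stratify_by = NULL) {
  if (!nrow(annotations)) ps_stop("no annotations to summarize")
  lev <- c("promoter", "intragenic", "distal_intergenic")
  if (is.null(stratify_by)) {
    cnt <- table(factor(annotations$region_class, levels = lev))
    data.frame(region_class = lev, n = as.integer(cnt),
               pct = round(100 * as.integer(cnt) / nrow(annotations), 1),
               stringsAsFactors = FALSE)
  } else if (identical(stratify_by, "biotype")) {
    bt <- ifelse(is.na(annotations$assigned_biotype), "unassigned",
                 annotations$assigned_biotype)
    tab <- table(bt, factor(annotations$region_class, levels = lev))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("biotype", "region_class", "n")
    tot <- stats::ave(df$n, df$biotype, FUN = sum)
    df$pct <- ifelse(tot > 0, round(100 * df$n / tot, 1), 0)
    df
  } else ps_stop("stratify_by must be NULL or 'biotype'")
}

#' Write peak annotations as TSV
#' @param annotations output of [classify_peaks()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  con <- ps_connection(path, "w")
  on.exit(close(con))
  utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
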