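#' Classify differential-expression rows
#'
#' The log2 fold change is mutant relative to control, so genes the
#' factor activates are *higher in control* and carry negative values.
#' Rows whose larger genotype mean is below `min_mean_count` are
#' "filtered"; otherwise "activated" when `log2fc <= -lfc_threshold` and
#' `fdr < fdr_threshold`, "repressed" when `log2fc >= lfc_threshold` and
#' `fdr < fdr_threshold`, else "unchanged". The fold-change threshold is
#' inclusive, the FDR threshold strict.
#'
#' @param de DE data.frame (see [read_de_table()]).
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @param fdr_threshold FDR threshold.
#' @param min_mean_count minimum mean read count required in at least one
#'   genotype.
#' @return character vector of directions, one per row.
#' @export
classify_de <- function(de, lfc_threshold = 0.5, fdr_threshold = 0.05,
                        min_mean_count = 25) {
  stopifnot_cols(de, c("gene_id", "log2fc", "fdr", "mean_count_control",
                       "mean_count_mutant"), "DE table")
  if (anyNA(de$log2fc) || anyNA(de$fdr))
    ps_stop("DE table has missing log2fc or fdr values")
  expressed <- pmax(de$mean_count_control, de$mean_count_mutant) >=
    min_mean_count
  sig <- de$fdr < fdr_threshold
  ifelse(!expressed, "filtered",
         ifelse(sig & de$log2fc <= -lfc_threshold, "activated",
                ifelse(sig & de$log2fc >= lfc_threshold, "repressed",
                       "unchanged")))
}

#' Call direct target genes
#'
#' A gene is *bound* when it is the assigned (nearest-promoter) gene of
#' at least one peak, optionally restricted to assignments within
#' `max_tss_distance` bp of the TSS. A *direct* target is a bound gene
#' classified activated or repressed.
#'
#' @param de DE data.frame.
#' @param annotations peak annotations from [classify_peaks()].
#' @param lfc_threshold,fdr_threshold,min_mean_count passed to
#'   [classify_de()].
#' @param max_tss_distance optional cap (bp) on the peak-to-TSS distance
#'   that counts as binding.
#' @return object of class `target_calls`: list with `calls` (per-gene
#'   data.frame: `gene_id`, `direction`, `bound`, `direct`) and `summary`
#'   (counts and percentages of direct targets; percentages rounded to
#'   one decimal).
#' @export
call_direct_targets <- function(de, annotations, lfc_threshold = 0.5,
                                fdr_threshold = 0.05, min_mean_count = 25,
                                max_tss_distance = NULL) {
  direction <- classify_de(de, lfc_threshold, fdr_threshold, min_mean_count)
  ann <- annotations
  if (!is.null(max_tss_distance))
    ann <- ann[!is.na(ann$distance_to_tss) &
                 abs(ann$distance_to_tss) <= max_tss_distance, ,
               drop = FALSE]
  bound_genes <- unique(stats::na.omit(ann$assigned_gene))
  calls <- data.frame(
    gene_id = de$gene_id, direction = direction,
    bound = de$gene_id %in% bound_genes, stringsAsFactors = FALSE)
  calls$direct <- calls$bound & direction %in% c("activated", "repressed")
  structure(list(calls = calls, summary = target_summary(calls)),
            class = "target_calls")
}

target_summary <- function(calls) {
  n_act <- sum(calls$direction == "activated")
  n_rep <- sum(calls$direction == "repressed")
  nd_act <- sum(calls$direct & calls$direction == "activated")
  nd_rep <- sum(calls$direct & calls$direction == "repressed")
  list(n_activated = n_act, n_repressed = n_rep,
       n_direct_activated = nd_act, n_direct_repressed = nd_rep,
       pct_direct_activated = if (n_act) round(100 * nd_act / n_act, 1) else NA,
       pct_direct_repressed = if (n_rep) round(100 * nd_rep / n_rep, 1) else NA)
}

#' @export
print.target_calls <- function(x, ...) {
  s <- x$summary
  cat("Direct target calls\n")
  cat(sprintf("  activated: %d, of which bound (direct): %d (%s%%)\n",
              s$n_activated, s$n_direct_activated,
              format(s$pct_direct_activated)))
  cat(sprintf("  repressed: %d, of which bound (direct): %d (%s%%)\n",
              s$n_repressed, s$n_direct_repressed,
              format(s$pct_direct_repressed)))
  invisible(x)
}

#' @export
summary.target_calls <- function(object, ...) object$summary
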