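test_that("generators are byte-deterministic under a fixed seed and independent across streams", {
  cfg <- synthetic_config(seed = 3)
  g1 <- generate_annotation(cfg)
  g2 <- generate_annotation(cfg)
  expect_identical(g1, g2)
  p1 <- generate_peaks(g1, cfg)
  expect_identical(p1, generate_peaks(g1, cfg))
  # full study write-out is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # different seeds change the draws
  expect_false(identical(p1, generate_peaks(g1, synthetic_config(seed = 4))))
})

test_that("generated annotations respect packing, spacing and biotype constraints", {
  cfg <- synthetic_config(seed = 5, n_genes = 60)
  g <- generate_annotation(cfg)
  expect_equal(nrow(g), 60)
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(diff(gg$start) >= (gg$end - gg$start)[-nrow(gg)] + 3400))
    expect_true(all(gg$start >= 3400))
    expect_true(all(gg$end <= cfg$chrom_lengths[[ch]]))
  }
  # exons nest inside genes
  for (i in seq_len(nrow(g))) {
    es <- as.integer(strsplit(g$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(g$exon_ends[i], ",")[[1]])
    expect_true(all(es >= g$start[i] & ee <= g$end[i] & es < ee))
    expect_true(all(diff(es) > 0))
  }
  # degenerate biotype mix
  cfg_pc <- synthetic_config(seed = 5, biotype_mix = c(
    protein_coding = 1, lncRNA = 0, miRNA = 0, pseudogene = 0, other = 0))
  expect_true(all(generate_annotation(cfg_pc)$biotype == "protein_coding"))
  # infeasible packing errors out
  expect_error(generate_annotation(synthetic_config(
    seed = 1, chrom_lengths = c(chr1 = 5e4), n_genes = 50)), "pack")
})

test_that("planted region classes are recovered by the classifier", {
  cfg1 <- synthetic_config(seed = 6, n_peaks = 200, region_mix = c(
    promoter = 1, intragenic = 0, distal = 0))
  g <- generate_annotation(cfg1)
  ann <- classify_peaks(generate_peaks(g, cfg1), g)
  expect_true(all(ann$region_class == "promoter"))
  cfg0 <- synthetic_config(seed = 6, n_peaks = 0)
  expect_equal(nrow(generate_peaks(g, cfg0)), 0)
})

test_that("colocalized peak generation hits the planted bin structure", {
  cfg <- synthetic_config(seed = 8)
  g <- generate_annotation(cfg)
  A <- generate_peaks(g, cfg)
  # theta = 0: B avoids every A-hit bin entirely
  B0 <- generate_colocalized_peaks(A, cfg$chrom_lengths, 0, cfg)
  expect_equal(count_peak_overlaps(A, B0)$n_overlapping_A, 0L)
  ct <- binned_contingency(A, B0, cfg$chrom_lengths)
  expect_equal(ct$a, 0L)
  expect_error(generate_colocalized_peaks(A, cfg$chrom_lengths, -2, cfg),
               ">= 0")
})

test_that("coverage generation plants the configured fold enrichment", {
  cfg <- synthetic_config(seed = 9, enrichment_fold = 4,
                          background_rate = 0.05)
  g <- generate_annotation(cfg)
  pk <- generate_peaks(g, cfg)
  sig_idx <- seq_len(250)
  tr <- generate_coverage(pk[sig_idx, ], cfg)
  r <- rpkm_at_peaks(pk, tr, flank = 1000)
  med_sig <- median(r$rpkm[sig_idx])
  med_bg <- median(r$rpkm[-sig_idx])
  expect_gt(med_sig / med_bg, 2.5)
  # empty track contract
  cfg0 <- synthetic_config(seed = 9, background_rate = 0,
                           enrichment_fold = 1)
  tr0 <- generate_coverage(pk[0, ], cfg0)
  expect_equal(sum(lengths(tr0$reads)), 0)
})

test_that("DE generation plants targets within bounds and flags violations", {
  cfg <- synthetic_config(seed = 12)
  g <- generate_annotation(cfg)
  bound <- g$gene_id[1:150]
  det <- generate_de_table(g, bound, cfg)
  expect_equal(nrow(det$de), nrow(g))
  planted <- det$truth$gene_id[det$truth$status %in%
                                 c("direct_activated", "direct_repressed")]
  expect_true(all(planted %in% bound))
  act <- det$de[det$de$gene_id %in%
                  det$truth$gene_id[det$truth$status == "direct_activated"], ]
  expect_true(all(act$log2fc <= -cfg$lfc_effect & act$fdr < 0.05))
  rep_ <- det$de[det$de$gene_id %in%
                   det$truth$gene_id[det$truth$status == "direct_repressed"], ]
  expect_true(all(rep_$log2fc >= cfg$lfc_effect & rep_$fdr < 0.05))
  # more planted targets than bound genes is an error
  expect_error(generate_de_table(g, g$gene_id[1:40], cfg), "bound genes")
})

test_that("planted motif instances are found at the configured fraction", {
  cfg <- synthetic_config(seed = 15, motif_fraction = 0.4, n_peaks = 300)
  g <- generate_annotation(cfg)
  pk <- generate_peaks(g, cfg)
  gs <- generate_genome_sequence(pk, cfg)
  r <- peaks_with_motif(pk, gs)
  planted <- attr(gs, "planted")
  expect_equal(length(planted), 120)
  hits <- r$per_peak$name[r$per_peak$n_hits > 0]
  # every planted peak is recovered (instances are centered on summits)
  expect_true(mean(planted %in% hits) > 0.97)
  expect_lt(abs(r$fraction_with_motif - 0.4), 0.05)
})

test_that("synthetic configs validate their mixes", {
  expect_error(synthetic_config(region_mix = c(promoter = 0.5,
                                               intragenic = 0.5,
                                               distal = 0.5)), "sum to 1")
  expect_error(synthetic_config(biotype_mix = c(protein_coding = 2,
                                                lncRNA = -1, miRNA = 0,
                                                pseudogene = 0, other = 0)))
})
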