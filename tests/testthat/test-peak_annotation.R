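test_that("region classification follows the promoter/intragenic/distal boundary rules", {
  genes <- gene_df("chr1", 5000, 8000, "+")
  # 3 kb upstream window of a plus-strand TSS
  a <- classify_peaks(peak_df("chr1", 3400, 3600), genes)
  expect_equal(a$region_class, "promoter")
  expect_equal(a$distance_to_tss, -1500)
  # <= 300 bp downstream of the TES is intragenic
  b <- classify_peaks(peak_df("chr1", 8100, 8300), genes)
  expect_equal(b$region_class, "intragenic")
  expect_equal(b$subregion, "downstream<=300")
  # far away is distal
  d <- classify_peaks(peak_df("chr1", 19900, 20100), genes)
  expect_equal(d$region_class, "distal_intergenic")
  # minus-strand gene: upstream lies to the right of end - 1
  gm <- gene_df("chr1", 5000, 8000, "-")
  m <- classify_peaks(peak_df("chr1", 8400, 8600), gm)
  expect_equal(m$region_class, "promoter")
  expect_equal(m$distance_to_tss, -501)
})

test_that("boundary positions honor the half-open window definitions", {
  genes <- gene_df("chr1", 5000, 8000, "+")
  cls_at <- function(pt)
    classify_peaks(peak_df("chr1", pt, pt + 1, summit = pt), genes)$region_class
  expect_equal(cls_at(2000), "promoter")        # exactly TSS - 3000
  expect_equal(cls_at(1999), "distal_intergenic")
  expect_equal(cls_at(5000), "intragenic")      # the TSS itself is in the body
  expect_equal(cls_at(8299), "intragenic")      # TES + 300
  expect_equal(cls_at(8300), "distal_intergenic")
})

test_that("summit takes precedence over midpoint as the classification point", {
  genes <- gene_df("chr1", 5000, 8000, "+")
  # midpoint would be distal; summit sits in the promoter
  p <- peak_df("chr1", 2500, 20000, summit = 3500L)
  expect_equal(classify_peaks(p, genes)$region_class, "promoter")
})

test_that("empty gene set makes every peak distal and unassigned", {
  a <- classify_peaks(peak_df("chr1", c(100, 5000), c(200, 5100)),
                      gene_df("chr9", integer(0), integer(0), character(0)))
  expect_equal(a$region_class, rep("distal_intergenic", 2))
  expect_true(all(is.na(a$assigned_gene)))
})

test_that("nearest-promoter assignment breaks ties lexicographically", {
  genes <- gene_df("chr1", c(5000, 11000), c(8000, 14000), c("+", "+"),
                   gene_id = c("geneB", "geneA"))
  # nearest TSS wins: |10000-11000| = 1000 < |10000-5000| = 5000
  a <- classify_peaks(peak_df("chr1", 9990, 10010, summit = 10000L), genes)
  expect_equal(a$assigned_gene, "geneA")
  # exactly equidistant from two minus-strand TSSs, outside every window
  gm <- gene_df("chr1", c(1000, 9000), c(4000, 12000), c("-", "-"),
                gene_id = c("geneD", "geneC"))
  b <- classify_peaks(peak_df("chr1", 7995, 8005, summit = 7999L), gm)
  expect_equal(b$region_class, "distal_intergenic")
  expect_equal(b$assigned_gene, "geneC") # ties: lexicographically smallest
})

test_that("peaks nearest a pseudogene inside a gene body are reassigned to the host", {
  genes <- rbind(
    gene_df("chr1", 5000, 50000, "+", gene_id = "geneX"),
    gene_df("chr1", 20000, 21000, "+", gene_id = "pseudoP",
            biotype = "pseudogene"))
  a <- classify_peaks(peak_df("chr1", 21490, 21510, summit = 21500L), genes)
  expect_equal(a$region_class, "intragenic")
  expect_equal(a$assigned_gene, "geneX")
  # outside any body, the pseudogene keeps the assignment
  g2 <- gene_df("chr1", c(20000, 100000), c(21000, 110000), "+",
                gene_id = c("pseudoP", "geneY"),
                biotype = c("pseudogene", "protein_coding"))
  b <- classify_peaks(peak_df("chr1", 25000, 25100), g2)
  expect_equal(b$assigned_gene, "pseudoP")
})

test_that("single-gene genomes assign every peak to that gene", {
  genes <- gene_df("chr1", 5000, 8000, "+", gene_id = "only")
  pk <- peak_df("chr1", c(0, 4000, 6000, 50000), c(10, 4100, 6100, 50100))
  expect_equal(unique(classify_peaks(pk, genes)$assigned_gene), "only")
})

test_that("classification agrees with the brute-force oracle on random genomes", {
  for (seed in 1:12) {
    fx <- random_fixture(seed)
    got <- classify_peaks(fx$peaks, fx$genes)$region_class
    expect_equal(got, oracle_classify(fx$peaks, fx$genes),
                 info = paste("seed", seed))
  }
})

test_that("every peak gets exactly one region class and counts partition the input", {
  fx <- random_fixture(99, n_peaks = 120)
  ann <- classify_peaks(fx$peaks, fx$genes)
  expect_equal(nrow(ann), nrow(fx$peaks))
  s <- summarize_regions(ann)
  expect_equal(sum(s$n), nrow(fx$peaks))
  expect_equal(sum(s$pct), 100, tolerance = 0.2)
})

test_that("region classes are invariant under coordinate reflection with strand flip", {
  for (seed in c(5, 17)) {
    fx <- random_fixture(seed)
    ann <- classify_peaks(fx$peaks, fx$genes)
    ann_r <- classify_peaks(reflect_peaks(fx$peaks, fx$L),
                            reflect_genes(fx$genes, fx$L))
    expect_equal(table(ann_r$region_class), table(ann$region_class))
  }
})

test_that("summarize_regions reports counts, percentages and biotype strata", {
  genes <- gene_df("chr1", 5000, 8000, "+")
  pk <- rbind(peak_df("chr1", rep(3000, 3), rep(3200, 3)),      # promoter
              peak_df("chr1", rep(6000, 4), rep(6200, 4)),      # intragenic
              peak_df("chr1", rep(50000, 3), rep(50200, 3)))    # distal
  pk$name <- sprintf("p%02d", 1:10)
  s <- summarize_regions(classify_peaks(pk, genes))
  expect_equal(s$pct, c(30, 40, 30))
  s2 <- summarize_regions(classify_peaks(pk, genes), stratify_by = "biotype")
  expect_true("protein_coding" %in% s2$biotype)
  expect_error(summarize_regions(classify_peaks(pk, genes), "foo"))
  expect_error(summarize_regions(empty_annotation <- classify_peaks(
    peak_df("chr1", integer(0), integer(0)), genes)), "summarize")
})

test_that("the max_tss_distance cap leaves far peaks unassigned", {
  genes <- gene_df("chr1", 5000, 8000, "+")
  far <- peak_df("chr1", 100000, 100200)
  expect_equal(classify_peaks(far, genes)$assigned_gene, "g001")
  expect_true(is.na(classify_peaks(far, genes,
                                   max_tss_distance = 50000)$assigned_gene))
})

test_that("subregions distinguish first exon, internal exon and intron", {
  genes <- gene_df("chr1", 5000, 9000, "+",
                   exon_starts = "5000,7000,8500",
                   exon_ends = "5500,7400,9000")
  sub_at <- function(pt)
    classify_peaks(peak_df("chr1", pt, pt + 1, summit = pt), genes)$subregion
  expect_equal(sub_at(5200), "5UTR-proxy:first-exon")
  expect_equal(sub_at(7200), "exon")
  expect_equal(sub_at(6000), "intron")
  # on the minus strand the first exon in transcription order is the last block
  gm <- gene_df("chr1", 5000, 9000, "-",
                exon_starts = "5000,8500", exon_ends = "5500,9000")
  sub_m <- function(pt)
    classify_peaks(peak_df("chr1", pt, pt + 1, summit = pt), gm)$subregion
  expect_equal(sub_m(8700), "5UTR-proxy:first-exon")
  expect_equal(sub_m(5200), "exon")
})
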