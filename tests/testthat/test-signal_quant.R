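track_from <- function(pos, lib = NULL, chrom = "chr1", label = "t")
  coverage_track(setNames(list(pos), chrom), library_size = lib, label = label)

test_that("rpkm follows count / window_kb / (library/1e6)", {
  # 500-bp peak, 1-kb flank -> 2.5-kb window; 10 reads; 1e6 library
  pk <- peak_df("chr1", 10000, 10500)
  tr <- track_from(seq(9500, 11000, length.out = 10), lib = 1e6)
  sig <- rpkm_at_peaks(pk, tr, flank = 1000)
  expect_equal(sig$count, 10)
  expect_equal(sig$rpkm, 10 / 2.5 / 1)
  # zero reads in window
  tr0 <- track_from(50000, lib = 1e6)
  expect_equal(rpkm_at_peaks(pk, tr0)$rpkm, 0)
})

test_that("rpkm is invariant under joint rescaling of counts and library size", {
  pk <- peak_df("chr1", 10000, 10500)
  pos <- seq(9500, 11000, length.out = 20)
  r1 <- rpkm_at_peaks(pk, track_from(pos, lib = 1e5))$rpkm
  r2 <- rpkm_at_peaks(pk, track_from(rep(pos, 2), lib = 2e5))$rpkm
  expect_equal(r1, r2)
})

test_that("windows truncate at chromosome edges with recomputed widths", {
  pk <- peak_df("chr1", 0, 500) # left flank would be negative
  tr <- track_from(c(100, 400, 900), lib = 1e6)
  sig <- rpkm_at_peaks(pk, tr, flank = 1000, genome = c(chr1 = 1000))
  expect_equal(sig$width, 1000)
  expect_equal(sig$rpkm, 3 / 1 / 1)
})

test_that("summit anchoring and window membership follow the read-anchor rule", {
  pk <- peak_df("chr1", 1000, 2000, summit = 1200L)
  tr <- track_from(c(1150, 1251, 1900), lib = 1e6)
  # summit +/- 50: [1150, 1251) holds only the read at 1150
  sig <- rpkm_at_peaks(pk, tr, flank = 50, anchor = "summit")
  expect_equal(sig$count, 1)
})

test_that("peak-centered profiles localize reads and conserve counts", {
  pk <- peak_df("chr1", c(5000, 9000), c(5400, 9400),
                summit = c(5200L, 9200L))
  pos <- c(5200, 5201, 5202, 9150, 3600)
  tr <- track_from(pos, lib = 1e6)
  m <- peak_centered_profile(pk, tr, half_window = 2000, bin_width = 50)
  expect_equal(dim(m), c(2, 80))
  # conservation: per-row bin counts sum to reads within the window
  counts <- m * (50 / 1000) * (1e6 / 1e6)
  expect_equal(sum(counts[1, ]), 4) # 3 at summit + 1 at 3600 (in window)
  expect_equal(sum(counts[2, ]), 1)
  # single read at the summit occupies exactly one bin
  m1 <- peak_centered_profile(pk[2, ], track_from(9200, lib = 1e6), 2000, 50)
  expect_equal(sum(m1 > 0), 1)
  expect_equal(colnames(m1)[which(m1 > 0)], "0")
})

test_that("profiles agree with an unindexed per-read loop oracle", {
  fx <- withr::with_seed(21, {
    s <- sample(2000:80000, 15)
    list(pk = peak_df("chr1", s, s + 300, summit = s + 150L),
         pos = sample(0:90000, 80))
  })
  tr <- track_from(fx$pos, lib = 1e6)
  m <- peak_centered_profile(fx$pk, tr, half_window = 1000, bin_width = 100)
  for (i in seq_len(nrow(fx$pk))) {
    ctr <- fx$pk$summit[i]
    for (b in 0:19) {
      lo <- ctr - 1000 + b * 100; hi <- lo + 100
      cnt <- sum(fx$pos >= lo & fx$pos < hi)
      expect_equal(m[i, b + 1] * (100 / 1000), cnt)
    }
  }
})

test_that("uniform coverage yields a flat mean peak-centered profile", {
  withr::with_seed(33, {
    s <- sample(5000:995000, 1000)
    pos <- sample(0:1e6, 3e5, replace = TRUE)
  })
  pk <- peak_df("chr1", s, s + 300, summit = s + 150L)
  m <- peak_centered_profile(pk, track_from(pos), 2000, 50)
  cm <- colMeans(m)
  expect_lt(max(cm) / min(cm), 1.2)
})

test_that("reads planted at summits make the center bin strictly maximal", {
  withr::with_seed(34, {
    s <- sample(5000:95000, 200)
    bg <- sample(0:1e5, 2000, replace = TRUE)
  })
  pk <- peak_df("chr1", s, s + 300, summit = s + 150L)
  m <- peak_centered_profile(pk, track_from(c(bg, pk$summit, pk$summit)),
                             2000, 50)
  cm <- colMeans(m)
  expect_equal(names(which.max(cm)), "0")
  expect_gt(max(cm), 1.5 * max(cm[names(cm) != "0"]))
})

test_that("metagene profiles scale bodies, keep flanks fixed and reverse minus strands", {
  g <- gene_df("chr1", 10000, 20000, "+")
  # uniform coverage: flat profile
  tr <- track_from(seq(5000, 25000, by = 10), lib = 1e6)
  m <- metagene_profile(g, tr, flank = 3000, flank_bins = 100, body_bins = 100)
  expect_equal(ncol(m), 300)
  expect_lt(max(m) / min(m), 1.3)
  # reads only in [TSS-500, TSS): confined to the last 17 upstream bins
  tr2 <- track_from(seq(9500, 9999, by = 5), lib = 1e6)
  m2 <- metagene_profile(g, tr2, 3000, 100, 100)
  nz <- which(m2[1, ] > 0)
  expect_true(all(nz >= 84 & nz <= 100)) # 500 bp / 30 bp-per-bin = 17 bins
  expect_true(all(m2[1, 101:300] == 0))
  # minus-strand gene with reads at its TSS: signal on the TSS side
  gm <- gene_df("chr1", 10000, 20000, "-") # TSS at 19999
  tr3 <- track_from(seq(19900, 19990, by = 10), lib = 1e6)
  m3 <- metagene_profile(gm, tr3, 3000, 100, 100)
  nz3 <- which(m3[1, ] > 0)
  expect_true(all(nz3 <= 110) && length(nz3) > 0)
})

test_that("short genes are skipped with a warning", {
  g <- rbind(gene_df("chr1", 10000, 20000, "+", gene_id = "long"),
             gene_df("chr1", 30000, 30050, "+", gene_id = "short"))
  expect_warning(m <- metagene_profile(g, track_from(15000), body_bins = 100),
                 "skipped")
  expect_equal(rownames(m), "long")
})

test_that("stratified enrichment summarizes per-label distributions", {
  sig <- data.frame(name = sprintf("p%02d", 1:6), track = "t",
                    count = 1, width = 1000,
                    rpkm = c(4, 4, 4, 8, 2, 4))
  s <- stratified_enrichment(sig, c(rep("a", 3), rep("b", 3)))
  expect_equal(s$median[s$stratum == "a"], 4)
  expect_equal(s$iqr[s$stratum == "a"], 0)
  expect_equal(s$median[s$stratum == "b"], 4)
  # single-element stratum
  s1 <- stratified_enrichment(sig[1, ], "solo")
  expect_equal(s1$median, 4)
  expect_error(stratified_enrichment(sig, c("a", "b")), "label")
})
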