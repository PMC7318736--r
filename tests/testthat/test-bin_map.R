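# Sliding-window genotype calling, bin construction, merge/filter rules and
# segment extraction.

test_that("window calls follow the 80% majority rule", {
  # 10 SNPs inside [0, 50kb): 9 donor + 1 recipient -> donor; 5/5 -> het
  p <- bin_params(min_snps = 5)
  g <- tiny_genome(c(c1 = 1e5))
  tab <- mk_snps(seq(1000, 46000, by = 5000), c(rep(2, 9), 0))
  w <- call_windows(tab, "L1", "c1", g, p)
  expect_identical(w$call[1], 2L)
  tab <- mk_snps(seq(1000, 46000, by = 5000), c(rep(2, 5), rep(0, 5)))
  w <- call_windows(tab, "L1", "c1", g, p)
  expect_identical(w$call[1], 1L)
  # empty window -> NA
  tab <- mk_snps(c(60000, 61000, 62000, 63000, 64000), rep(2, 5))
  w <- call_windows(tab, "L1", "c1", g, p)
  expect_true(is.na(w$call[1]))
})

test_that("het calls count toward the denominator but neither parent", {
  # 3 donor + 7 het: donor fraction 0.3 of informative -> het window
  g <- tiny_genome(c(c1 = 1e5))
  tab <- mk_snps(seq(1000, 46000, by = 5000), c(rep(2, 3), rep(1, 7)))
  w <- call_windows(tab, "L1", "c1", g, bin_params())
  expect_identical(w$call[1], 1L)
})

test_that("run boundaries sit at the midpoint of the transition overlap", {
  # 10 donor then 10 recipient windows, 50 kb / 5 kb: boundary at
  # start of window 10 (45 kb) + (5 + 50)/2 kb = 72.5 kb
  p <- bin_params()
  w <- data.frame(start = seq(0, by = 5000, length.out = 20),
                  end = seq(0, by = 5000, length.out = 20) + 50000,
                  call = c(rep(2L, 10), rep(0L, 10)),
                  n_snps = 50L)
  b <- windows_to_bins(w, chrom_length = 145000, params = p)
  expect_equal(nrow(b), 2L)
  expect_equal(b$end[1], 72500)
  expect_equal(b$start[2], 72500)
  expect_equal(b$start[1], 0)
  expect_equal(b$end[2], 145000)
})

test_that("uniform windows give a single chromosome-spanning bin", {
  w <- data.frame(start = seq(0, by = 5000, length.out = 30),
                  end = seq(0, by = 5000, length.out = 30) + 50000,
                  call = 2L, n_snps = 10L)
  b <- windows_to_bins(w, 195000, bin_params())
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end, b$genotype), c(0, 195000, 2))
})

test_that("merge_and_filter fuses near bins, drops short ones, idempotently", {
  p <- bin_params()
  # donor, 80 kb recipient gap, donor -> one donor bin
  b <- mk_bins(c(5e5, 8e4, 5e5), c(2, 0, 2))
  m <- merge_and_filter(b, p)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end, m$genotype), c(0, 1.08e6, 2))
  # isolated 95 kb donor bin -> NA
  b <- mk_bins(c(5e5, 9.5e4, 5e5), c(0, 2, 0))
  m <- merge_and_filter(b, p)
  expect_true(all(is.na(m$genotype[m$start == 5e5])))
  # 120 kb gap is NOT merged
  b <- mk_bins(c(5e5, 1.2e5, 5e5), c(2, 0, 2))
  m <- merge_and_filter(b, p)
  expect_equal(sum(m$genotype == 2, na.rm = TRUE), 2L)
  # idempotence on a messy tiling
  b <- mk_bins(c(3e5, 5e4, 2e5, 9e4, 4e5, 1.5e5, 6e4), c(2, 0, 2, NA, 0, 2, 0))
  once <- merge_and_filter(b, p)
  twice <- merge_and_filter(once, p)
  expect_equal(once, twice)
  # tiling is preserved
  expect_equal(sum(once$end - once$start), sum(b$end - b$start))
})

test_that("alternating single-window runs are removed by the length filter", {
  p <- bin_params()
  w <- data.frame(start = seq(0, by = 5000, length.out = 40),
                  end = seq(0, by = 5000, length.out = 40) + 50000,
                  call = rep(c(2L, 0L), 20), n_snps = 10L)
  b <- windows_to_bins(w, 245000, p)
  m <- merge_and_filter(b, p)
  expect_true(all(is.na(m$genotype)) || all(m$end - m$start >= p$min_bin |
                                              is.na(m$genotype)))
})

test_that("filter_alleles drops monomorphic sites and third alleles", {
  gt <- matrix(c("A/A", "T/T", "A/T", "C/C",
                 "A/A", "A/A", "T/T", "G/G"), ncol = 2,
               dimnames = list(NULL, c("L1", "L2")))
  sites <- data.frame(chrom = "c1", pos = c(100, 200, 300, 400),
                      donor_gt = c("T/T", "T/T", "T/T", "G/G"),
                      recipient_gt = c("A/A", "A/A", "A/A", "G/G"))
  suppressMessages(tab <- filter_alleles(gt, sites))
  expect_equal(nrow(tab$snps), 3L)  # monomorphic G/G site dropped
  expect_equal(tab$geno[, "L1"], c(0L, 2L, 1L))
  expect_equal(tab$geno[, "L2"], c(0L, 0L, 2L))
  # third allele -> missing
  gt2 <- matrix(c("C/C"), 1, 1, dimnames = list(NULL, "L1"))
  sites2 <- data.frame(chrom = "c1", pos = 1, donor_gt = "T/T",
                       recipient_gt = "A/A")
  suppressMessages(tab2 <- filter_alleles(gt2, sites2))
  expect_true(is.na(tab2$geno[1, 1]))
  # identical parents genome-wide -> abort
  sites3 <- data.frame(chrom = "c1", pos = 1:2, donor_gt = "A/A",
                       recipient_gt = "A/A")
  gt3 <- matrix("A/A", 2, 1, dimnames = list(NULL, "L1"))
  expect_error(suppressMessages(filter_alleles(gt3, sites3)), "identical|informative")
})

test_that("bins tile each chromosome exactly and are order-invariant", {
  cfg <- sim_config(chr_lengths = c(c1 = 5e6, c2 = 5e6), n_lines = 4,
                    segments_per_line = c(1, 2), segment_length = c(5e5, 2e6),
                    seed = 23)
  pop <- simulate_population(cfg)
  bins <- call_bins(pop$snp, pop$genome)
  for (l in unique(bins$line)) for (ch in pop$genome$chrom) {
    b <- bins[bins$line == l & bins$chrom == ch, ]
    expect_equal(sum(b$end - b$start), unname(cfg$chr_lengths[ch]))
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }
  # shuffling SNP input order does not change the bins
  idx <- sample(nrow(pop$snp$snps))
  tab2 <- snp_table(pop$snp$snps[idx, ], pop$snp$geno[idx, , drop = FALSE])
  expect_equal(call_bins(tab2, pop$genome), bins)
})

test_that("bins_to_segments keeps donor and het bins only", {
  b <- cbind(line = "L1", chrom = "c1",
             mk_bins(c(1e6, 2.5e6, 1e6, 5e5), c(0, 2, 1, NA)))
  s <- bins_to_segments(b)
  expect_equal(nrow(s), 2L)
  expect_equal(s$state, c("donor", "het"))
  expect_equal(s$length[1], 2.5e6)
  # background-only line: no segments
  b0 <- cbind(line = "L1", chrom = "c1", mk_bins(c(2e6, 1e6), c(0, NA)))
  expect_equal(nrow(bins_to_segments(b0)), 0L)
})

test_that("planted segments are recovered on a noisy population", {
  cfg <- sim_config(chr_lengths = c(c1 = 2e7, c2 = 2e7), n_lines = 10,
                    segments_per_line = c(1, 3), segment_length = c(5e5, 5e6),
                    genotyping_error = 0.01, missing_rate = 0.05, seed = 41)
  pop <- simulate_population(cfg)
  gr <- gr_map(pop$snp, pop$genome)
  rec <- recovery_errors(pop$truth$segments, gr$segments)
  expect_true(all(!is.na(rec$boundary)))
  expect_true(all(rec$boundary <= 50000))
  if (nrow(rec$spurious))
    expect_true(all(rec$spurious$end - rec$spurious$start < 2e5))
})
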