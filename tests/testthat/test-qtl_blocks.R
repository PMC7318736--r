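# Block partitioning and the stepwise likelihood-ratio QTL scan.

test_that("partition cuts at segment boundaries and tracks carriers", {
  g <- tiny_genome(c(c1 = 2e7))
  segs <- data.frame(line = c("A", "B"), chrom = "c1",
                     start = c(0, 5e6), end = c(1e7, 1.5e7), state = "donor")
  bs <- partition_blocks(segs, g)
  expect_equal(nrow(bs$blocks), 3L)
  expect_equal(bs$blocks$start, c(0, 5e6, 1e7))
  expect_equal(unname(bs$dosage["A", ]), c(1, 1, 0))
  expect_equal(unname(bs$dosage["B", ]), c(0, 1, 1))
  # one line, one segment -> one block
  bs1 <- partition_blocks(segs[1, ], g)
  expect_equal(nrow(bs1$blocks), 1L)
  # identical segments in two lines -> one block with both carriers
  segs2 <- data.frame(line = c("A", "B"), chrom = "c1", start = 0, end = 1e7,
                      state = "donor")
  bs2 <- partition_blocks(segs2, g)
  expect_equal(nrow(bs2$blocks), 1L)
  expect_equal(bs2$blocks$n_carriers, 2)
  # het dosage is 0.5
  segs3 <- data.frame(line = "A", chrom = "c1", start = 0, end = 1e7,
                      state = "het")
  expect_equal(unname(partition_blocks(segs3, g)$dosage["A", 1]), 0.5)
})

test_that("partition is order-invariant and lengths sum to union coverage", {
  g <- tiny_genome(c(c1 = 2e7, c2 = 2e7))
  set.seed(8)
  segs <- data.frame(line = sample(sprintf("L%d", 1:10), 25, TRUE),
                     chrom = sample(c("c1", "c2"), 25, TRUE),
                     start = round(runif(25, 0, 1.5e7)))
  segs$end <- pmin(segs$start + round(runif(25, 2e5, 4e6)), 2e7)
  segs$state <- "donor"
  # segments of one line may overlap here; dosage is still well-defined (max)
  bs1 <- partition_blocks(segs, g, lines = sprintf("L%d", 1:10))
  bs2 <- partition_blocks(segs[sample(nrow(segs)), ], g,
                          lines = sprintf("L%d", 1:10))
  expect_equal(bs1$blocks, bs2$blocks)
  expect_equal(bs1$dosage, bs2$dosage)
  cov <- union_coverage(segs, g)
  expect_equal(sum(bs1$blocks$length),
               cov$union_length[cov$scope == "total"])
})

test_that("a noise-free separable block gives capped LOD and exact effect", {
  g <- tiny_genome(c(c1 = 2e7))
  lines <- sprintf("L%02d", 1:20)
  segs <- data.frame(line = lines[1:10], chrom = "c1", start = 0, end = 1e6,
                     state = "donor")
  bs <- partition_blocks(segs, g, lines = lines)
  blups <- data.frame(line = lines, y = rep(c(2, 0), each = 10))
  q <- scan_qtl(bs, blups, lod_threshold = 2.5, lod_cap = 50)
  expect_equal(nrow(q), 1L)
  expect_equal(q$lod, 50)
  expect_equal(q$add_effect, 1.0)
  expect_equal(q$qtl, "q-Yc1")
  # sign flip
  qf <- scan_qtl(bs, blups, sign_flip = TRUE)
  expect_equal(qf$add_effect, -1.0)
})

test_that("LOD agrees with an independent lm/F-statistic oracle", {
  set.seed(12)
  g <- tiny_genome(c(c1 = 2e7))
  lines <- sprintf("L%03d", 1:80)
  segs <- data.frame(line = lines[1:20], chrom = "c1", start = 0, end = 1e6,
                     state = "donor")
  bs <- partition_blocks(segs, g, lines = lines)  # a single block: no cofactors
  blups <- null_blups(bs, sigma = 1, a = 0.8, qtl_block = "block1")
  q <- scan_qtl(bs, blups, lod_threshold = 0)
  # oracle: plain lm on the same regressor, LOD from RSS ratio and from the
  # 1-df F statistic must agree with the scan's value
  d <- data.frame(y = blups$y, x2 = 2 * bs$dosage[, 1])
  f1 <- lm(y ~ x2, d)
  rss0 <- sum((d$y - mean(d$y))^2)
  rss1 <- sum(residuals(f1)^2)
  n <- nrow(d)
  lod_rss <- n / 2 * log10(rss0 / rss1)
  Fst <- summary(f1)$fstatistic[["value"]]
  lod_f <- n / 2 * log10(1 + Fst / f1$df.residual)
  expect_equal(q$lod, lod_rss)
  expect_equal(q$lod, lod_f)
  expect_equal(q$add_effect, unname(coef(f1)["x2"]))
  expect_equal(q$pve, 100 * (rss0 - rss1) / rss0)
})

test_that("planted-QTL LOD stochastically dominates the permuted scan", {
  set.seed(33)
  bs <- mk_block_set(n_lines = 150, k = 6, p_carry = 0.2)
  blups <- null_blups(bs, sigma = 1, a = 1, qtl_block = "block3")
  q1 <- scan_qtl(bs, blups, lod_threshold = 0)
  perm <- blups
  perm$y <- sample(perm$y)
  q0 <- scan_qtl(bs, perm, lod_threshold = 0)
  expect_gt(max(q1$lod), max(c(q0$lod, 0)))
})

test_that("PVE is bounded and sums sensibly for orthogonal noise-free blocks", {
  g <- tiny_genome(c(c1 = 2e7))
  lines <- sprintf("L%02d", 1:24)
  # carrier sets chosen so the centered dosages are exactly orthogonal:
  # cov = 6/24 - (12/24)*(12/24) = 0
  segs <- rbind(
    data.frame(line = lines[1:12], chrom = "c1", start = 0, end = 1e6,
               state = "donor"),
    data.frame(line = lines[c(1:6, 13:18)], chrom = "c1", start = 2e6,
               end = 3e6, state = "donor"))
  bs <- partition_blocks(segs, g, lines = lines)
  y <- 2 * bs$dosage[, 1] + 1 * bs$dosage[, 2]
  blups <- data.frame(line = lines, y = y)
  q <- scan_qtl(bs, blups, lod_threshold = 0)
  expect_true(all(q$pve >= 0 & q$pve <= 100))
  expect_lte(sum(q$pve), 100 + 1e-8)
})

test_that("degenerate blocks are skipped or dropped with a notice", {
  g <- tiny_genome(c(c1 = 2e7))
  lines <- sprintf("L%02d", 1:12)
  segs <- rbind(
    data.frame(line = lines, chrom = "c1", start = 0, end = 1e6,
               state = "donor"),                       # constant dosage 1
    data.frame(line = lines[1:4], chrom = "c1", start = 2e6, end = 3e6,
               state = "donor"),
    data.frame(line = lines[1:4], chrom = "c1", start = 5e6, end = 6e6,
               state = "donor"))                       # collinear with above
  bs <- partition_blocks(segs, g, lines = lines)
  blups <- data.frame(line = lines, y = rnorm(12))
  expect_warning(
    expect_message(scan_qtl(bs, blups), "collinear"),
    "constant dosage")
})

test_that("QTL names follow the q-TRAITCHR pattern with ordinal suffixes", {
  g <- tiny_genome(c(c1 = 2e7))
  lines <- sprintf("L%02d", 1:30)
  segs <- rbind(
    data.frame(line = lines[1:10], chrom = "c1", start = 0, end = 1e6,
               state = "donor"),
    data.frame(line = lines[11:20], chrom = "c1", start = 5e6, end = 6e6,
               state = "donor"))
  bs <- partition_blocks(segs, g, lines = lines)
  y <- 3 * bs$dosage[, 1] - 3 * bs$dosage[, 2] + rnorm(30, 0, 0.1)
  q <- scan_qtl(bs, data.frame(line = lines, fl = y))
  expect_equal(sort(q$qtl), c("q-FLc1-1", "q-FLc1-2"))
})
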