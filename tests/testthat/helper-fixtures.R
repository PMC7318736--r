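# Shared builders for small in-code fixtures.

# One- or two-chromosome genome, bp (and proportional cM at 2 cM/Mb).
tiny_genome <- function(lens = c(c1 = 1e7), cm_per_mb = 2) {
  genome_map(names(lens), length_bp = lens, length_cm = lens / 1e6 * cm_per_mb)
}

# Marker table on one chromosome from a vector of calls at given cM positions.
mk_markers <- function(calls, cm, chrom = "c1", line = "L1") {
  mk <- data.frame(marker = sprintf("m%d", seq_along(cm)), chrom = chrom,
                   cm = cm, stringsAsFactors = FALSE)
  m <- matrix(calls, ncol = 1, dimnames = list(mk$marker, line))
  marker_table(mk, m)
}

# SNP table on one chromosome from explicit positions and per-line codes.
mk_snps <- function(pos, codes, chrom = "c1", line = "L1") {
  snps <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  g <- matrix(as.integer(codes), ncol = 1, dimnames = list(NULL, line))
  snp_table(snps, g)
}

# Tiled bin data frame for one line/chromosome from widths and genotypes.
mk_bins <- function(widths, genos, start0 = 0) {
  ends <- start0 + cumsum(widths)
  data.frame(start = c(start0, head(ends, -1)), end = ends,
             genotype = as.integer(genos), n_snps = 10L)
}

# Match recovered segments (donor+het pooled) against planted truth: for each
# truth segment return the largest boundary error of the overlapping called
# interval (NA when nothing overlaps), plus called intervals with no truth
# overlap (potential spurious segments).
recovery_errors <- function(truth, called) {
  err <- vapply(seq_len(nrow(truth)), function(i) {
    s <- called[called$line == truth$line[i] & called$chrom == truth$chrom[i] &
                  called$start < truth$end[i] & called$end > truth$start[i], ,
                drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    max(abs(min(s$start) - truth$start[i]), abs(max(s$end) - truth$end[i]))
  }, numeric(1))
  spur <- vapply(seq_len(nrow(called)), function(i) {
    tr <- truth[truth$line == called$line[i] & truth$chrom == called$chrom[i] &
                  truth$start < called$end[i] & truth$end > called$start[i], ,
                drop = FALSE]
    nrow(tr) == 0
  }, logical(1))
  list(boundary = err, spurious = called[spur, , drop = FALSE])
}

# Line-level response for QTL scan tests: y = 2a * x + N(0, sigma).
null_blups <- function(blocks, sigma = 1, a = 0, qtl_block = NULL) {
  y <- stats::rnorm(length(blocks$lines), 0, sigma)
  if (!is.null(qtl_block)) y <- y + 2 * a * blocks$dosage[, qtl_block]
  data.frame(line = blocks$lines, y = y, stringsAsFactors = FALSE)
}

# Block set with `k` disjoint 1-Mb blocks; each line carries each block
# independently with probability p_carry (dosage 1).
mk_block_set <- function(n_lines = 300, k = 12, p_carry = 0.1) {
  lines <- sprintf("L%03d", seq_len(n_lines))
  segs <- list()
  for (j in seq_len(k)) {
    carriers <- lines[stats::runif(n_lines) < p_carry]
    if (!length(carriers)) carriers <- lines[j]
    segs[[j]] <- data.frame(line = carriers, chrom = "c1",
                            start = (j - 1) * 1e6, end = j * 1e6,
                            state = "donor", stringsAsFactors = FALSE)
  }
  partition_blocks(do.call(rbind, segs), tiny_genome(c(c1 = 2e7)),
                   lines = lines)
}
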