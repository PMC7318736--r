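#' SNP genotype table
#'
#' Container for population SNP genotypes coded against the two parents:
#' 0 = recipient-homozygous, 1 = heterozygous, 2 = donor-homozygous,
#' NA = missing. Positions are 0-based bp and strictly increasing within each
#' chromosome; parent alleles must differ at every retained site.
#'
#' @param snps data frame with columns `chrom`, `pos` and optionally
#'   `donor_allele`, `recipient_allele`.
#' @param geno integer matrix, one row per SNP, one column per line.
#' @return An object of class `snp_table`: list with `snps`, `geno`, `lines`.
#' @export
snp_table <- function(snps, geno) {
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)),
            nrow(snps) == nrow(geno))
  if (is.null(colnames(geno))) stop("geno must have line names as columns")
  ord <- order(match(snps$chrom, unique(snps$chrom)), snps$pos)
  if (is.unsorted(ord)) {  # normalise input order
    snps <- snps[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    rownames(snps) <- NULL
  }
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on %s", ch))
  }
  if (!is.null(snps$donor_allele) &&
      any(snps$donor_allele == snps$recipient_allele))
    stop("parent alleles identical at some retained sites")
  storage.mode(geno) <- "integer"
  structure(list(snps = snps, geno = geno, lines = colnames(geno)),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs on %d chromosomes x %d lines\n",
              nrow(x$snps), length(unique(x$snps$chrom)), length(x$lines)))
  invisible(x)
}

#' Parameters of the sliding-window bin caller
#'
#' Defaults follow the resequencing bin-map procedure for CSSLs: 50 kb windows
#' advanced in 5 kb steps, a window called homozygous for a parent when more
#' than 80% of its informative SNPs carry that parent's genotype (otherwise
#' heterozygous), bins shorter than 100 kb filtered, and same-genotype bins
#' separated by less than 100 kb merged.
#'
#' @param window window size in bp.
#' @param step step size in bp (must not exceed `window`).
#' @param threshold majority fraction in (0.5, 1] for a homozygous call.
#' @param min_bin minimum bin length in bp; shorter bins are set to NA.
#' @param merge_gap same-genotype bins separated by less than this are fused.
#' @param min_snps minimum informative SNPs for a window call (else NA).
#' @return list of class `bin_params`.
#' @export
bin_params <- function(window = 50000, step = 5000, threshold = 0.8,
                       min_bin = 100000, merge_gap = 100000, min_snps = 5) {
  stopifnot(window > 0, step > 0, step <= window,
            threshold > 0.5, threshold <= 1,
            min_bin >= 0, merge_gap >= 0, min_snps >= 1)
  structure(list(window = window, step = step, threshold = threshold,
                 min_bin = min_bin, merge_gap = merge_gap,
                 min_snps = min_snps), class = "bin_params")
}

#' Filter line calls against the parental alleles
#'
#' Sites where the two parents carry the same genotype are dropped (they carry
#' no ancestry information); at retained sites, any line genotype composed of
#' alleles other than the two parental ones is set to missing. Line genotypes
#' matching the donor, the recipient, or one allele of each are coded 2, 0 and
#' 1 respectively.
#'
#' @param gt character matrix of raw genotypes, one row per site, one column
#'   per line; entries like `"A/A"`, `"A/T"` (separator `/` or `|`), or NA.
#' @param sites data frame with `chrom`, `pos` (0-based) and parent genotype
#'   columns `donor_gt`, `recipient_gt` holding the parents' alleles (e.g.
#'   `"A/A"`); heterozygous or missing parent sites are dropped.
#' @return A [snp_table()] of the retained sites. Counts of dropped sites are
#'   reported with a message.
#' @export
filter_alleles <- function(gt, sites) {
  stopifnot(nrow(gt) == nrow(sites),
            all(c("chrom", "pos", "donor_gt", "recipient_gt") %in% names(sites)))
  split_gt <- function(g) strsplit(g, "[/|]")
  one_allele <- function(g) {
    a <- split_gt(g)
    vapply(a, function(v) {
      if (length(v) == 0 || anyNA(v) || any(v == ".")) return(NA_character_)
      if (length(unique(v)) != 1L) return(NA_character_)  # het parent
      v[1]
    }, character(1))
  }
  don <- one_allele(sites$donor_gt)
  rec <- one_allele(sites$recipient_gt)
  keep <- !is.na(don) & !is.na(rec) & don != rec
  n_parent_drop <- sum(is.na(don) | is.na(rec))
  n_mono <- sum(!is.na(don) & !is.na(rec) & don == rec)
  if (!any(keep)) stop("no informative sites: parents identical or missing genome-wide")
  if (n_mono == nrow(sites)) stop("parent columns identical genome-wide")
  sites <- sites[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  don <- don[keep]; rec <- rec[keep]

  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  al <- split_gt(as.vector(gt))
  codes <- vapply(seq_along(al), function(k) {
    v <- al[[k]]
    i <- (k - 1L) %% nrow(gt) + 1L
    if (length(v) == 0 || anyNA(v) || any(v == ".")) return(NA_integer_)
    if (any(!v %in% c(don[i], rec[i]))) return(NA_integer_)  # third allele
    nd <- sum(v == don[i])
    if (nd == length(v)) GENO_DONOR
    else if (nd == 0) GENO_RECIPIENT
    else GENO_HET
  }, integer(1))
  geno[] <- codes
  message(sprintf(
    "filter_alleles: kept %d sites (dropped %d parent-missing/het, %d monomorphic)",
    sum(keep), n_parent_drop, n_mono))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    donor_allele = don, recipient_allele = rec,
                    stringsAsFactors = FALSE)
  snp_table(out, geno)
}

#' Call sliding-window genotypes for one line on one chromosome
#'
#' Windows of `params$window` bp are anchored every `params$step` bp from the
#' chromosome start. Within each window the fraction of SNPs carrying the
#' donor (resp. recipient) homozygous genotype is computed over all
#' informative (non-missing) calls; heterozygous calls count toward the
#' denominator but toward neither parent, so a truly heterozygous region
#' cannot be tipped into a homozygous call by a handful of miscalls. A window
#' with fewer than `min_snps` informative SNPs is NA; otherwise it is donor-
#' or recipient-homozygous when the corresponding fraction exceeds
#' `threshold`, and heterozygous otherwise.
#'
#' @param tab a [snp_table()].
#' @param line line name (column of `tab$geno`).
#' @param chrom chromosome name.
#' @param genome a [genome_map()].
#' @param params a [bin_params()].
#' @return data frame with `start`, `end` (window span, unclipped), `call`
#'   (0/1/2/NA) and `n_snps` (informative SNPs).
#' @export
call_windows <- function(tab, line, chrom, genome, params = bin_params()) {
  clen <- chrom_lengths(genome, chrom)
  sel <- tab$snps$chrom == chrom
  pos <- tab$snps$pos[sel]
  g <- tab$geno[sel, line]
  starts <- seq(0, clen - 1, by = params$step)
  if (length(pos) == 0) {
    return(data.frame(start = starts, end = starts + params$window,
                      call = NA_integer_, n_snps = 0L))
  }
  cum <- function(v) c(0L, cumsum(v))
  cd <- cum(!is.na(g) & g == GENO_DONOR)
  cr <- cum(!is.na(g) & g == GENO_RECIPIENT)
  ch <- cum(!is.na(g) & g == GENO_HET)
  lo <- findInterval(starts - 1, pos)
  hi <- findInterval(starts + params$window - 1, pos)
  nd <- cd[hi + 1L] - cd[lo + 1L]
  nr <- cr[hi + 1L] - cr[lo + 1L]
  nh <- ch[hi + 1L] - ch[lo + 1L]
  inf <- nd + nr + nh
  call <- rep(GENO_HET, length(starts))
  fd <- ifelse(inf > 0, nd / inf, 0)
  fr <- ifelse(inf > 0, nr / inf, 0)
  call[fd > params$threshold] <- GENO_DONOR
  call[fr > params$threshold] <- GENO_RECIPIENT
  call[inf < params$min_snps] <- NA_integer_
  data.frame(start = starts, end = starts + params$window,
             call = as.integer(call), n_snps = as.integer(inf))
}

#' Convert a window-call sequence to recombination bins
#'
#' Maximal runs of identical window calls become bins. The breakpoint between
#' two adjacent runs is placed at the midpoint of the overlap between the last
#' window of the left run and the first window of the right run (the symmetric
#' choice; with step `s` and window `w` this is `start_left + (s + w) / 2`).
#' The first bin starts at 0 and the last ends at the chromosome length, so
#' bins tile the chromosome exactly.
#'
#' @param windows output of [call_windows()].
#' @param chrom_length chromosome length in bp.
#' @param params a [bin_params()] (supplies window/step).
#' @return data frame with `start`, `end`, `genotype` (0/1/2/NA), `n_snps`
#'   (sum of window support within the run).
#' @export
windows_to_bins <- function(windows, chrom_length, params = bin_params()) {
  if (nrow(windows) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      genotype = integer(0), n_snps = integer(0)))
  key <- ifelse(is.na(windows$call), -1L, windows$call)
  r <- rle(key)
  ends_idx <- cumsum(r$lengths)          # last window index of each run
  starts_idx <- ends_idx - r$lengths + 1L
  n <- length(r$lengths)
  # breakpoint after run k: midpoint of overlap of windows ends_idx[k] and
  # ends_idx[k]+1, i.e. start_left + (step + window)/2
  brk <- windows$start[ends_idx[-n]] + (params$step + params$window) / 2
  brk <- pmin(pmax(brk, 0), chrom_length)
  start <- c(0, brk)
  end <- c(brk, chrom_length)
  geno <- ifelse(r$values < 0, NA_integer_, r$values)
  ns <- vapply(seq_len(n), function(k)
    sum(windows$n_snps[starts_idx[k]:ends_idx[k]]), numeric(1))
  keep <- end > start  # degenerate runs squeezed out by clamping
  data.frame(start = start, end = end, genotype = as.integer(geno),
             n_snps = as.integer(ns))[keep, , drop = FALSE]
}

# Merge adjacent bins with equal genotype (NA matches NA).
rle_merge_bins <- function(b) {
  if (nrow(b) <= 1) return(b)
  key <- ifelse(is.na(b$genotype), -1L, b$genotype)
  grp <- cumsum(c(TRUE, diff(key) != 0))
  out <- data.frame(
    start = tapply(b$start, grp, min),
    end = tapply(b$end, grp, max),
    genotype = b$genotype[!duplicated(grp)],
    n_snps = as.integer(tapply(b$n_snps, grp, sum)))
  rownames(out) <- NULL
  out
}

#' Merge nearby same-genotype bins and filter short bins
#'
#' Applies the bin clean-up rules in order: (1) when two bins of the same
#' called genotype are separated by less than `merge_gap` of other called
#' genotype, the gap is absorbed into that genotype (repeated to a fixed
#' point); (2) called bins shorter than `min_bin` are set to NA ("not
#' available"); (3) adjacent bins of equal genotype are re-fused. NA regions
#' created by step (2) are never re-absorbed, which makes the operation
#' idempotent.
#'
#' @param bins tiled, ordered bins for one line on one chromosome
#'   (data frame with `start`, `end`, `genotype`, `n_snps`).
#' @param params a [bin_params()].
#' @return bins after merging and filtering; still a tiling of the chromosome.
#' @export
merge_and_filter <- function(bins, params = bin_params()) {
  b <- rle_merge_bins(bins)
  # stage 1: absorb short called gaps between same-genotype neighbours
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= nrow(b) - 2L) {
      g <- b$genotype[i]
      if (!is.na(g)) {
        j <- i + 1L
        while (j <= nrow(b) && !identical(b$genotype[j], g)) j <- j + 1L
        if (j <= nrow(b)) {
          between <- (i + 1L):(j - 1L)
          gapw <- sum(b$end[between] - b$start[between])
          if (!anyNA(b$genotype[between]) && gapw < params$merge_gap) {
            b$genotype[between] <- g
            b <- rle_merge_bins(b)
            changed <- TRUE
            next  # re-examine from same i after merge
          }
        }
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  # stage 2: short called bins become NA
  short <- !is.na(b$genotype) & (b$end - b$start) < params$min_bin
  b$genotype[short] <- NA_integer_
  # stage 3: re-fuse
  rle_merge_bins(b)
}

#' Build the recombination bin map for a population
#'
#' Runs [call_windows()], [windows_to_bins()] and [merge_and_filter()] for
#' every line and chromosome and returns the tiled bins.
#'
#' @param tab a [snp_table()].
#' @param genome a [genome_map()].
#' @param params a [bin_params()].
#' @param lines lines to process (default: all columns of `tab$geno`).
#' @return data frame of bins: `line`, `chrom`, `start`, `end`, `genotype`
#'   (0/1/2/NA), `n_snps`.
#' @export
call_bins <- function(tab, genome, params = bin_params(), lines = tab$lines) {
  res <- vector("list", length(lines) * nrow(genome))
  k <- 0L
  for (l in lines) {
    for (ch in genome$chrom) {
      w <- call_windows(tab, l, ch, genome, params)
      b <- windows_to_bins(w, chrom_lengths(genome, ch), params)
      b <- merge_and_filter(b, params)
      if (nrow(b)) {
        k <- k + 1L
        res[[k]] <- cbind(data.frame(line = l, chrom = ch,
                                     stringsAsFactors = FALSE), b)
      }
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Extract donor introgression segments from bins
#'
#' Donor-homozygous and heterozygous bins become introgression segments
#' carrying their state; recipient and NA bins do not. Lines whose bins are
#' all recipient/NA yield no segments.
#'
#' @param bins bins from [call_bins()] (or a single line/chromosome tiling
#'   with `line`/`chrom` columns).
#' @return data frame of segments: `line`, `chrom`, `start`, `end`, `state`
#'   ("donor" or "het"), `length`, `n_snps`.
#' @export
bins_to_segments <- function(bins) {
  keep <- !is.na(bins$genotype) & bins$genotype %in% c(GENO_DONOR, GENO_HET)
  s <- bins[keep, , drop = FALSE]
  out <- data.frame(line = s$line, chrom = s$chrom, start = s$start,
                    end = s$end,
                    state = ifelse(s$genotype == GENO_DONOR, "donor", "het"),
                    length = s$end - s$start,
                    n_snps = s$n_snps, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sequencing-based segment map (GR map) in one call
#'
#' Convenience wrapper: bin map plus segment extraction.
#'
#' @inheritParams call_bins
#' @return list with `bins` and `segments`.
#' @export
gr_map <- function(tab, genome, params = bin_params(), lines = tab$lines) {
  bins <- call_bins(tab, genome, params, lines)
  list(bins = bins, segments = bins_to_segments(bins))
}
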