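# Coverage and density statistics comparing the marker map and the
# sequencing map. Interval unions are delegated to IRanges::reduce on an
# integer-scaled copy of the coordinates.

# Union length of [start, end) intervals (numeric, same unit). `scale` maps
# the unit onto integers (1 for bp; 1e4 keeps 2-dp cM exact).
interval_union_length <- function(start, end, scale = 1) {
  if (length(start) == 0) return(0)
  ir <- IRanges::IRanges(start = as.integer(round(start * scale)) + 1L,
                         end = as.integer(round(end * scale)))
  sum(IRanges::width(IRanges::reduce(ir))) / scale
}

#' Union genome coverage of a segment population
#'
#' For each chromosome, the union over all lines of their donor intervals is
#' computed; the coverage rate is union length / chromosome length x 100.
#' Subgenome and Total rows aggregate the union and chromosome lengths before
#' dividing, so an aggregate rate is the length-weighted rate of its members.
#'
#' @param segments data frame with `chrom`, `start`, `end` (0-based half-open,
#'   any one unit) and optionally `line`; typically from [bins_to_segments()]
#'   or [call_marker_segments()].
#' @param genome a [genome_map()] with lengths in the matching unit.
#' @param unit `"bp"` or `"cm"`.
#' @return data frame of class `coverage_report`: `scope` ("chromosome",
#'   "subgenome", "total"), `chrom`, `n_segments`, `union_length`, `length`,
#'   `coverage_rate` (percent, rounded half-up to 2 dp).
#' @examples
#' g <- genome_map("c1", length_bp = 1e7)
#' segs <- data.frame(chrom = "c1", start = c(0, 5e5), end = c(1e6, 2e6))
#' union_coverage(segs, g)  # union 2 Mb, rate 20.00
#' @export
union_coverage <- function(segments, genome, unit = c("bp", "cm")) {
  unit <- match.arg(unit)
  scale <- if (unit == "bp") 1 else 1e4
  lens <- chrom_lengths(genome, genome$chrom, unit)
  if (nrow(segments)) {
    if (any(segments$start < 0) ||
        any(segments$end > chrom_lengths(genome, segments$chrom, unit) + 1e-9))
      stop("segment outside chromosome bounds")
  }
  per <- data.frame(scope = "chromosome", chrom = genome$chrom,
                    length = lens, stringsAsFactors = FALSE)
  per$n_segments <- vapply(genome$chrom, function(ch)
    sum(segments$chrom == ch), numeric(1))
  per$union_length <- vapply(genome$chrom, function(ch) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    interval_union_length(s$start, s$end, scale)
  }, numeric(1))
  agg <- NULL
  if (!is.null(genome$subgenome)) {
    agg <- do.call(rbind, lapply(unique(genome$subgenome), function(sg) {
      m <- per[genome$subgenome == sg, , drop = FALSE]
      data.frame(scope = "subgenome", chrom = sg, length = sum(m$length),
                 n_segments = sum(m$n_segments),
                 union_length = sum(m$union_length))
    }))
  }
  tot <- data.frame(scope = "total", chrom = "Total", length = sum(per$length),
                    n_segments = sum(per$n_segments),
                    union_length = sum(per$union_length))
  out <- rbind(per, agg, tot)
  out$coverage_rate <- round_half_up(out$union_length / out$length * 100, 2)
  out <- out[, c("scope", "chrom", "n_segments", "union_length", "length",
                 "coverage_rate")]
  rownames(out) <- NULL
  class(out) <- c("coverage_report", "data.frame")
  out
}

#' Coverage rate from pre-tabulated lengths
#'
#' Percentage of a map covered, rounded half-up to 2 dp as in published
#' coverage tables: `union_length / total_length * 100`.
#'
#' @param union_length effective (union) coverage length.
#' @param total_length map length in the same unit.
#' @return percentage, 2 dp.
#' @export
coverage_rate <- function(union_length, total_length) {
  round_half_up(union_length / total_length * 100, 2)
}

#' Fold coverage of a segment population
#'
#' Total segment length summed over all lines (overlaps counted as many times
#' as they occur) divided by total genome length: how many genome-equivalents
#' of donor material the population carries.
#'
#' @inheritParams union_coverage
#' @return a single ratio.
#' @export
fold_coverage <- function(segments, genome, unit = c("bp", "cm")) {
  unit <- match.arg(unit)
  sum(segments$end - segments$start) /
    sum(chrom_lengths(genome, genome$chrom, unit))
}

#' Map-comparison report from per-chromosome summaries
#'
#' Builds the standard genetic-map vs physical-map comparison table from
#' per-chromosome inputs: marker spacing (cM/marker), SNP density (SNPs/kb)
#' and coverage rates for each chromosome, each subgenome and the whole
#' genome. Aggregate rows sum lengths, counts and coverage before dividing. A
#' worked example ships with the package: a published interspecific cotton
#' CSSL map summary (26 chromosomes, 515 SSR markers, 11.65 million SNPs) in
#' `system.file("extdata", "cotton_cssl_table1.tsv", package = "cssltools")`.
#'
#' @param d data frame with columns `chrom`, `subgenome`, `mm_len_cm`,
#'   `gr_len_mb`, `n_markers`, `n_snps`, `mm_n_segments`, `gr_n_segments`,
#'   `mm_cov_cm`, `gr_cov_mb`.
#' @return data frame with the input columns plus `mm_cm_per_marker`,
#'   `gr_snps_per_kb` (1 dp) and `mm_rate`, `gr_rate` (percent, 2 dp), with
#'   appended subgenome and Total rows.
#' @export
map_comparison <- function(d) {
  need <- c("chrom", "subgenome", "mm_len_cm", "gr_len_mb", "n_markers",
            "n_snps", "mm_n_segments", "gr_n_segments", "mm_cov_cm",
            "gr_cov_mb")
  stopifnot(all(need %in% names(d)))
  agg <- function(rows, label) {
    data.frame(chrom = label, subgenome = label,
               mm_len_cm = sum(rows$mm_len_cm),
               gr_len_mb = sum(rows$gr_len_mb),
               n_markers = sum(rows$n_markers), n_snps = sum(rows$n_snps),
               mm_n_segments = sum(rows$mm_n_segments),
               gr_n_segments = sum(rows$gr_n_segments),
               mm_cov_cm = sum(rows$mm_cov_cm),
               gr_cov_mb = sum(rows$gr_cov_mb), stringsAsFactors = FALSE)
  }
  sub <- do.call(rbind, lapply(unique(d$subgenome), function(sg)
    agg(d[d$subgenome == sg, ], sg)))
  out <- rbind(d[need], sub, agg(d, "Total"))
  out$mm_cm_per_marker <- density_stats(out$n_markers, out$mm_len_cm, "spacing")
  out$gr_snps_per_kb <- density_stats(out$n_snps, out$gr_len_mb, "density")
  out$mm_rate <- coverage_rate(out$mm_cov_cm, out$mm_len_cm)
  out$gr_rate <- coverage_rate(out$gr_cov_mb, out$gr_len_mb)
  rownames(out) <- NULL
  out
}

#' Marker spacing and SNP density
#'
#' `spacing`: map length per marker (e.g. cM/marker). `density`: markers per
#' kb of physical length (`length` given in Mb). Values are reported at 1 dp,
#' the convention of published map-comparison tables; zero markers give NA.
#'
#' @param n number of markers or SNPs (vector allowed).
#' @param length map length per entry: cM for `spacing`, Mb for `density`.
#' @param what `"spacing"` or `"density"`.
#' @param digits rounding for the reported value.
#' @return numeric vector.
#' @examples
#' density_stats(515, 4402.50, "spacing")      # 8.5 cM/marker
#' density_stats(11653661, 2233.05, "density") # 5.2 SNPs/kb
#' @export
density_stats <- function(n, length, what = c("spacing", "density"),
                          digits = 1) {
  what <- match.arg(what)
  v <- if (what == "spacing") ifelse(n > 0, length / n, NA_real_)
       else n / (length * 1000)
  round_half_up(v, digits)
}
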