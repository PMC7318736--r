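#' Construct a genome map
#'
#' A genome map is an ordered table of chromosomes with physical lengths (bp)
#' and, optionally, genetic lengths (cM) and a subgenome label. It anchors all
#' coordinate arithmetic in the package: segment calling, coverage statistics
#' and block partitioning all validate against it. For an allotetraploid such
#' as cultivated cotton the subgenome column distinguishes the At and Dt
#' chromosome sets so that coverage can be aggregated per subgenome.
#'
#' @param chrom character vector of chromosome names (unique, in genome order).
#' @param length_bp numeric vector of physical lengths in bp (> 0).
#' @param length_cm optional numeric vector of genetic lengths in cM (> 0).
#' @param subgenome optional character vector of subgenome labels (e.g. "At",
#'   "Dt").
#' @return A `data.frame` of class `genome_map` with columns `chrom`,
#'   `length_bp` and, when supplied, `length_cm` and `subgenome`.
#' @examples
#' genome_map(c("A01", "D01"), length_bp = c(2e7, 1.5e7),
#'            length_cm = c(120, 100), subgenome = c("At", "Dt"))
#' @export
genome_map <- function(chrom, length_bp, length_cm = NULL, subgenome = NULL) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (length(length_bp) != length(chrom)) stop("length_bp must match chrom")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("chromosome lengths must be positive")
  g <- data.frame(chrom = chrom, length_bp = as.numeric(length_bp),
                  stringsAsFactors = FALSE)
  if (!is.null(length_cm)) {
    if (length(length_cm) != length(chrom)) stop("length_cm must match chrom")
    if (any(!is.finite(length_cm)) || any(length_cm <= 0))
      stop("genetic lengths must be positive")
    g$length_cm <- as.numeric(length_cm)
  }
  if (!is.null(subgenome)) {
    if (length(subgenome) != length(chrom)) stop("subgenome must match chrom")
    g$subgenome <- as.character(subgenome)
  }
  class(g) <- c("genome_map", "data.frame")
  g
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %.2f Mb total", nrow(x),
              sum(x$length_bp) / 1e6))
  if (!is.null(x$length_cm)) cat(sprintf(", %.2f cM", sum(x$length_cm)))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Length lookup in the requested unit; errors on unknown chromosomes.
chrom_lengths <- function(genome, chrom, unit = c("bp", "cm")) {
  unit <- match.arg(unit)
  col <- if (unit == "bp") "length_bp" else "length_cm"
  if (is.null(genome[[col]]))
    stop(sprintf("genome map has no %s lengths", unit))
  i <- match(chrom, genome$chrom)
  if (anyNA(i))
    stop(sprintf("chromosome(s) absent from genome map: %s",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  genome[[col]][i]
}

# Round half away from zero, the convention used for reported percentages
# (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
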