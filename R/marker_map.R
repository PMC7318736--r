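#' SSR marker table
#'
#' Graphical genotypes of a population at sparse mapped markers. Calls are
#' coded `DD` (homozygous donor), `DR` (heterozygous), `RR` (homozygous
#' recipient) or NA (missing). Marker positions must be strictly increasing
#' within each chromosome.
#'
#' @param markers data frame with columns `marker`, `chrom` and at least one of
#'   `cm` (genetic position) and `bp` (physical position).
#' @param calls character matrix, one row per marker (in the same order), one
#'   column per line; entries in `DD`, `DR`, `RR`, NA.
#' @return An object of class `marker_table`: list with `markers`, `calls`,
#'   `lines`.
#' @export
marker_table <- function(markers, calls) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "chrom") %in% names(markers)),
            nrow(markers) == nrow(calls))
  if (is.null(markers$cm) && is.null(markers$bp))
    stop("markers need a cm and/or bp position column")
  if (is.null(colnames(calls))) stop("calls must have line names as columns")
  bad <- !is.na(calls) & !calls %in% c("DD", "DR", "RR")
  if (any(bad)) stop("marker calls must be DD, DR, RR or NA")
  poscol <- if (!is.null(markers$cm)) "cm" else "bp"
  for (ch in unique(markers$chrom)) {
    p <- markers[[poscol]][markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("marker positions not strictly increasing on %s", ch))
  }
  structure(list(markers = markers, calls = calls, lines = colnames(calls)),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d markers on %d chromosomes x %d lines\n",
              nrow(x$markers), length(unique(x$markers$chrom)),
              length(x$lines)))
  invisible(x)
}

# Segments for one line on one chromosome from non-missing calls at positions
# `pos` (missing markers have already been removed: they are transparent and
# never break a run). `clen` is the chromosome length in the same unit.
line_chrom_marker_segments <- function(calls, pos, clen) {
  donor <- calls != "RR"
  if (!any(donor)) return(NULL)
  r <- rle(donor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    dd <- idx[calls[idx] == "DD"]
    core <- if (length(dd)) range(pos[dd]) else range(pos[idx])
    state <- if (length(dd)) "donor" else "het"
    # flank anchors: nearest RR marker outside the run, else chromosome end
    left_rr <- if (starts[k] > 1L) pos[starts[k] - 1L] else NA_real_
    right_rr <- if (ends[k] < length(calls)) pos[ends[k] + 1L] else NA_real_
    # interior flanks contribute half their span; terminal flanks (run touches
    # a chromosome end) extend fully to the end
    start <- if (is.na(left_rr)) 0 else core[1] - (core[1] - left_rr) / 2
    end <- if (is.na(right_rr)) clen else core[2] + (right_rr - core[2]) / 2
    segs[[length(segs) + 1L]] <- data.frame(
      start = start, end = end, state = state,
      core_start = core[1], core_end = core[2],
      n_dd = length(dd), n_dr = sum(calls[idx] == "DR"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, segs)
}

#' Call introgression segments from SSR graphical genotypes
#'
#' Implements the 100/50/0 percent rule: the stretch between the outermost
#' donor-homozygous (DD) markers of a run counts fully as donor; each flank
#' between that core and the nearest recipient (RR) marker counts at half
#' length (it contains the unobserved breakpoint, possibly marked by a
#' heterozygous DR call); RR-to-RR stretches count as zero. A run containing
#' no DD marker (DR only) is called heterozygous, with the outermost DR
#' markers as its core. Missing calls are transparent: they never break a run.
#' A run touching a chromosome end extends fully to that end.
#'
#' @param table a [marker_table()].
#' @param genome a [genome_map()]; must carry lengths in the requested unit.
#' @param unit `"cm"` (default, the genetic-map scale of the marker map) or
#'   `"bp"`.
#' @return data frame of class `marker_segments`: `line`, `chrom`, `start`,
#'   `end`, `length` (estimated segment length, = `end - start`), `state`
#'   ("donor" if the run holds at least one DD marker, else "het"), `n_dd`,
#'   `n_dr`. Coordinates are in `unit`.
#' @examples
#' g <- genome_map("c1", length_bp = 4e7, length_cm = 40)
#' mk <- data.frame(marker = paste0("m", 1:4), chrom = "c1",
#'                  cm = c(0, 10, 20, 30))
#' calls <- matrix(c("RR", "DD", "DD", "RR"), ncol = 1,
#'                 dimnames = list(mk$marker, "L1"))
#' call_marker_segments(marker_table(mk, calls), g)  # length 20 cM
#' @export
call_marker_segments <- function(table, genome, unit = c("cm", "bp")) {
  unit <- match.arg(unit)
  poscol <- if (unit == "cm") "cm" else "bp"
  if (is.null(table$markers[[poscol]]))
    stop(sprintf("marker table has no %s positions", unit))
  chroms <- unique(table$markers$chrom)
  chrom_lengths(genome, chroms, unit)  # errors on unknown chromosomes
  res <- list()
  for (l in table$lines) {
    any_call <- FALSE
    for (ch in chroms) {
      sel <- which(table$markers$chrom == ch)
      if (length(sel) < 2L)
        stop(sprintf("need at least 2 markers on chromosome %s", ch))
      calls <- table$calls[sel, l]
      pos <- table$markers[[poscol]][sel]
      known <- !is.na(calls)
      if (!any(known)) next
      any_call <- TRUE
      segs <- line_chrom_marker_segments(calls[known], pos[known],
                                         chrom_lengths(genome, ch, unit))
      if (!is.null(segs))
        res[[length(res) + 1L]] <- cbind(
          data.frame(line = l, chrom = ch, stringsAsFactors = FALSE), segs)
    }
    if (!any_call)
      warning(sprintf("line %s has no non-missing marker calls", l))
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(line = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), state = character(0),
               core_start = numeric(0), core_end = numeric(0),
               n_dd = integer(0), n_dr = integer(0))
  out$length <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  class(out) <- c("marker_segments", "data.frame")
  out
}

#' Summarise the marker-based segment map
#'
#' Per-chromosome and total segment counts and summed donor length (lengths
#' are summed over lines, so two lines carrying the same segment count twice;
#' use [union_coverage()] for the de-duplicated coverage).
#'
#' @param segments output of [call_marker_segments()].
#' @param genome a [genome_map()].
#' @return data frame with `chrom` (chromosome name or "Total"),
#'   `n_segments`, `donor_length`.
#' @export
mm_summary <- function(segments, genome) {
  unit <- attr(segments, "unit")
  if (is.null(unit)) unit <- "cm"
  per <- lapply(genome$chrom, function(ch) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, n_segments = nrow(s),
               donor_length = sum(s$length), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rbind(per, data.frame(chrom = "Total", n_segments = sum(per$n_segments),
                        donor_length = sum(per$donor_length)))
}
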