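# Block partition of a segment population and the block-based stepwise
# likelihood-ratio QTL scan.

#' Partition population segments into non-overlapping blocks
#'
#' The genome is cut at every segment boundary; within each resulting atomic
#' interval every line's donor dosage (0 recipient, 0.5 heterozygous, 1
#' donor-homozygous) is constant. Adjacent atomic intervals with identical
#' dosage vectors are merged, and intervals carried by no line are discarded.
#' Blocks are the unit of QTL testing: the sum of block lengths equals the
#' union coverage length of the population.
#'
#' @param segments data frame with `line`, `chrom`, `start`, `end` (bp) and
#'   `state` ("donor"/"het"); typically from [bins_to_segments()].
#' @param genome a [genome_map()].
#' @param lines the line universe (default: the lines appearing in
#'   `segments`). Pass the full population so that non-carrier lines get
#'   dosage 0 everywhere.
#' @return An object of class `block_set`: list with `blocks` (data frame
#'   `block_id`, `chrom`, `start`, `end`, `length`, `n_carriers`), `dosage`
#'   (matrix lines x blocks) and `lines`.
#' @examples
#' g <- genome_map("c1", 2e7)
#' segs <- data.frame(line = c("A", "B"), chrom = "c1",
#'                    start = c(0, 5e6), end = c(1e7, 1.5e7), state = "donor")
#' partition_blocks(segs, g)$blocks  # three blocks: A-only, A+B, B-only
#' @export
partition_blocks <- function(segments, genome, lines = NULL) {
  if (is.null(lines)) lines <- sort(unique(segments$line))
  if (!all(segments$line %in% lines))
    stop("segments carry lines outside the supplied line universe")
  chrom_lengths(genome, unique(segments$chrom))  # validate
  blocks <- list()
  dos <- list()
  for (ch in genome$chrom) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    cuts <- sort(unique(c(s$start, s$end)))
    a_start <- cuts[-length(cuts)]
    a_end <- cuts[-1]
    m <- matrix(0, nrow = length(lines), ncol = length(a_start),
                dimnames = list(lines, NULL))
    for (i in seq_len(nrow(s))) {
      cover <- a_start >= s$start[i] & a_end <= s$end[i]
      d <- if (s$state[i] == "donor") 1 else 0.5
      m[s$line[i], cover] <- pmax(m[s$line[i], cover], d)
    }
    carried <- colSums(m > 0) > 0
    a_start <- a_start[carried]; a_end <- a_end[carried]
    m <- m[, carried, drop = FALSE]
    if (!length(a_start)) next
    # merge contiguous atomic intervals with identical dosage vectors
    grp <- 1L
    grps <- integer(length(a_start))
    grps[1] <- grp
    for (k in seq_along(a_start)[-1]) {
      if (a_start[k] == a_end[k - 1] && all(m[, k] == m[, k - 1])) {
        grps[k] <- grp
      } else {
        grp <- grp + 1L
        grps[k] <- grp
      }
    }
    st <- tapply(a_start, grps, min)
    en <- tapply(a_end, grps, max)
    mm <- m[, !duplicated(grps), drop = FALSE]
    blocks[[ch]] <- data.frame(chrom = ch, start = as.numeric(st),
                               end = as.numeric(en), stringsAsFactors = FALSE)
    dos[[ch]] <- mm
  }
  if (!length(blocks)) stop("no segments to partition")
  bl <- do.call(rbind, blocks)
  dosage <- do.call(cbind, dos)
  bl$block_id <- sprintf("block%d", seq_len(nrow(bl)))
  colnames(dosage) <- bl$block_id
  bl$length <- bl$end - bl$start
  bl$n_carriers <- colSums(dosage > 0)
  bl <- bl[, c("block_id", "chrom", "start", "end", "length", "n_carriers")]
  rownames(bl) <- NULL
  structure(list(blocks = bl, dosage = dosage, lines = lines),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks on %d chromosomes x %d lines (mean %.2f Mb)\n",
              nrow(x$blocks), length(unique(x$blocks$chrom)), length(x$lines),
              mean(x$blocks$length) / 1e6))
  invisible(x)
}

# OLS fit returning rss and per-coefficient t-test p-values. X excludes the
# intercept (added here).
ols_fit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  r <- fit$rank
  rss <- sum(fit$residuals^2)
  df <- length(y) - r
  p <- rep(NA_real_, ncol(Xi))
  names(p) <- colnames(Xi)
  if (df > 0 && r > 0) {
    piv <- fit$qr$pivot[seq_len(r)]
    R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
    se <- sqrt(diag(chol2inv(R)) * rss / df)
    co <- fit$coefficients[piv]
    p[piv] <- 2 * stats::pt(-abs(co / se), df)
  }
  list(rss = rss, coef = fit$coefficients, p = p, rank = r)
}

# Forward-backward stepwise selection on columns of X (p-value entry/removal).
stepwise_select <- function(X, y, p_in = 0.05, p_out = 0.10, max_iter = 200) {
  sel <- integer(0)
  cand <- seq_len(ncol(X))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward
    pool <- setdiff(cand, sel)
    if (length(pool)) {
      pvals <- vapply(pool, function(j) {
        f <- ols_fit(X[, c(sel, j), drop = FALSE], y)
        unname(f$p[length(f$p)])
      }, numeric(1))
      best <- which.min(pvals)
      if (length(best) && !is.na(pvals[best]) && pvals[best] <= p_in) {
        sel <- c(sel, pool[best])
        changed <- TRUE
      }
    }
    # backward
    if (length(sel) > 0) {
      f <- ols_fit(X[, sel, drop = FALSE], y)
      pv <- f$p[-1]  # drop intercept
      worst <- which.max(pv)
      if (length(worst) && !is.na(pv[worst]) && pv[worst] >= p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(sel)
}

#' Block-based stepwise likelihood-ratio QTL scan
#'
#' An additive-only scan in the RSTEP-LRT-ADD mould. For each trait, (1)
#' forward-backward stepwise linear regression of the line values (typically
#' BLUPs) on block dosages selects background cofactors (entry `p_in`,
#' removal `p_out`); (2) each block `b` is then tested by comparing the
#' reduced model (selected cofactors minus `b`) with the full model (plus
#' `b`): \deqn{LOD_b = (n/2) \log_{10}(RSS_{reduced}/RSS_{full})} (3) the
#' additive effect `a` is the coefficient of the regressor `2x` (half the
#' fitted difference between the donor-homozygous and recipient classes) and
#' \deqn{PVE_b = 100 (RSS_{reduced} - RSS_{full}) / TSS.} Positive `a` means
#' the donor allele increases the trait; set `sign_flip = TRUE` for the
#' opposite orientation. Blocks reaching `lod_threshold` are reported and
#' named `q-<TRAIT><CHR>`, with an ordinal suffix when a trait has several QTL
#' on one chromosome.
#'
#' @param blocks a `block_set` from [partition_blocks()].
#' @param blups data frame with a `line` column and one numeric column per
#'   trait (e.g. `fit_blup()$blups`).
#' @param traits traits to scan (default: all non-line columns of `blups`).
#' @param p_in,p_out stepwise entry and removal p-values.
#' @param lod_threshold minimum LOD to report.
#' @param lod_cap LOD reported for numerically singular (zero-residual) fits.
#' @param sign_flip report `-a` instead of `a`.
#' @return data frame of class `qtl_result`: `trait`, `qtl`, `block`, `chrom`,
#'   `lod`, `pve`, `add_effect`, `start`, `end`.
#' @export
scan_qtl <- function(blocks, blups, traits = NULL, p_in = 0.05, p_out = 0.10,
                     lod_threshold = 2.5, lod_cap = 50, sign_flip = FALSE) {
  if (!inherits(blocks, "block_set")) stop("blocks must be a block_set")
  if (!"line" %in% names(blups)) stop("blups must carry a line column")
  if (is.null(traits)) traits <- setdiff(names(blups), "line")
  common <- intersect(blocks$lines, blups$line)
  if (length(common) < 3) stop("fewer than 3 lines are both genotyped and phenotyped")
  D <- blocks$dosage[common, , drop = FALSE]
  X <- 2 * D  # regressor 2x so the coefficient is the additive effect a
  n <- length(common)

  # blocks with constant dosage among phenotyped lines cannot be tested
  variable <- apply(X, 2, function(v) stats::var(v) > 0)
  if (any(!variable))
    warning(sprintf("%d block(s) with constant dosage skipped: %s",
                    sum(!variable),
                    paste(colnames(X)[!variable], collapse = ", ")))
  # collinear blocks: drop later duplicates from the cofactor pool
  Xv <- X[, variable, drop = FALSE]
  qrx <- qr(cbind(1, Xv))
  indep <- sort(setdiff(qrx$pivot[seq_len(qrx$rank)], 1L) - 1L)
  if (length(indep) < ncol(Xv))
    message(sprintf("scan_qtl: %d collinear block(s) dropped from cofactor pool",
                    ncol(Xv) - length(indep)))
  pool_ids <- colnames(Xv)[indep]

  out <- list()
  for (tr in traits) {
    y <- blups[[tr]][match(common, blups$line)]
    if (anyNA(y)) stop(sprintf("trait %s has missing values for scanned lines", tr))
    tss <- sum((y - mean(y))^2)
    Xpool <- X[, pool_ids, drop = FALSE]
    sel_idx <- stepwise_select(Xpool, y, p_in, p_out)
    sel_ids <- pool_ids[sel_idx]
    for (b in colnames(Xv)) {
      cof <- setdiff(sel_ids, b)
      # the tested block must be independent of its cofactors
      X0 <- X[, cof, drop = FALSE]
      rss0 <- ols_fit(X0, y)$rss
      f1 <- ols_fit(cbind(X0, X[, b, drop = FALSE]), y)
      rss1 <- f1$rss
      if (f1$rank <= ncol(X0) + 1L) {
        # tested block collinear with cofactors: no information
        next
      }
      lod <- if (rss1 <= .Machine$double.eps * tss) lod_cap
             else min(n / 2 * log10(rss0 / rss1), lod_cap)
      a <- unname(f1$coef[length(f1$coef)])
      if (sign_flip) a <- -a
      pve <- 100 * (rss0 - rss1) / tss
      if (!is.na(lod) && lod >= lod_threshold) {
        bi <- match(b, blocks$blocks$block_id)
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, block = b, chrom = blocks$blocks$chrom[bi],
          lod = lod, pve = pve, add_effect = a,
          start = blocks$blocks$start[bi], end = blocks$blocks$end[bi],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trait = character(0), block = character(0),
               chrom = character(0), lod = numeric(0), pve = numeric(0),
               add_effect = numeric(0), start = numeric(0), end = numeric(0))
  res <- res[order(match(res$trait, traits),
                   match(res$chrom, unique(res$chrom)), res$start), ,
             drop = FALSE]
  # QTL names: q-<TRAIT><CHR>, ordinal suffix when several per trait x chrom
  res$qtl <- character(nrow(res))
  if (nrow(res)) {
    key <- paste(res$trait, res$chrom)
    for (k in unique(key)) {
      i <- which(key == k)
      base <- sprintf("q-%s%s", toupper(res$trait[i[1]]), res$chrom[i[1]])
      res$qtl[i] <- if (length(i) == 1) base else
        sprintf("%s-%d", base, seq_along(i))
    }
  }
  res <- res[, c("trait", "qtl", "block", "chrom", "lod", "pve", "add_effect",
                 "start", "end")]
  rownames(res) <- NULL
  class(res) <- c("qtl_result", "data.frame")
  res
}
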