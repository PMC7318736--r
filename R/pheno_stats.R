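# Multi-environment phenotype statistics: BLUPs and broad-sense heritability
# from a REML mixed model, Pearson correlations between traits, and the
# weighted mean of additive effects (WAF).

#' BLUPs and broad-sense heritability per trait
#'
#' Fits, for each trait, the mixed model `value ~ env + (1 | line)` by REML
#' (environments fixed, lines random; replicates, when present, are pooled
#' into the residual). Line BLUPs are the grand mean of the fixed-effect
#' predictions plus the line random effect, and shrink toward the grand mean
#' relative to raw line means. Broad-sense heritability is computed on the
#' line-mean (across-environment repeatability) basis:
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / n_{env})}
#' Set `plot_basis = TRUE` for the plot-basis denominator
#' `sigma2_g + sigma2_e`.
#'
#' @param pheno long-format data frame with columns `line`, `env`, `trait`,
#'   `value` (e.g. from [simulate_phenotypes()] or [read_phenotypes()]).
#' @param traits traits to fit (default: all).
#' @param plot_basis use `sigma2_e` instead of `sigma2_e / n_env` in the H2
#'   denominator.
#' @return An object of class `blup_result`: list with `blups` (data frame,
#'   `line` plus one column per trait) and `varcomp` (data frame `trait`,
#'   `sigma2_g`, `sigma2_e`, `n_env`, `h2`). Traits observed in a single
#'   environment get `h2 = NA` with a warning.
#' @export
fit_blup <- function(pheno, traits = NULL, plot_basis = FALSE) {
  stopifnot(all(c("line", "env", "trait", "value") %in% names(pheno)))
  if (is.null(traits)) traits <- unique(pheno$trait)
  lines <- sort(unique(pheno$line))
  if (length(lines) < 2) stop("need at least 2 lines")
  blups <- data.frame(line = lines, stringsAsFactors = FALSE)
  vc <- list()
  for (tr in traits) {
    d <- pheno[pheno$trait == tr & !is.na(pheno$value), , drop = FALSE]
    n_env <- length(unique(d$env))
    if (n_env < 2) {
      warning(sprintf(
        "trait %s observed in a single environment: H2 not estimable", tr))
      mns <- tapply(d$value, d$line, mean)
      blups[[tr]] <- as.numeric(mns[match(lines, names(mns))])
      vc[[tr]] <- data.frame(trait = tr, sigma2_g = NA_real_,
                             sigma2_e = NA_real_, n_env = n_env,
                             h2 = NA_real_)
      next
    }
    d$line <- factor(d$line, levels = lines)
    d$env <- factor(d$env)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ env + (1 | line), data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    s2g <- as.numeric(lme4::VarCorr(fit)$line[1, 1])
    s2e <- stats::sigma(fit)^2
    fe <- lme4::fixef(fit)
    Xe <- stats::model.matrix(~env, data = data.frame(env = levels(d$env)))
    mu <- mean(Xe %*% fe)
    u <- lme4::ranef(fit)$line
    blup <- mu + u[match(lines, rownames(u)), 1]
    blup[is.na(blup)] <- mu  # lines absent for this trait sit at the mean
    blups[[tr]] <- blup
    denom <- if (plot_basis) s2g + s2e else s2g + s2e / n_env
    vc[[tr]] <- data.frame(trait = tr, sigma2_g = s2g, sigma2_e = s2e,
                           n_env = n_env,
                           h2 = if (denom > 0) s2g / denom else NA_real_)
  }
  structure(list(blups = blups, varcomp = do.call(rbind, vc)),
            class = "blup_result")
}

#' @export
print.blup_result <- function(x, ...) {
  cat(sprintf("blup_result: %d lines x %d traits\n", nrow(x$blups),
              ncol(x$blups) - 1L))
  print(x$varcomp, row.names = FALSE)
  invisible(x)
}

#' Pearson correlations between trait BLUPs
#'
#' Pairwise Pearson correlations over lines with two-tailed p-values and
#' significance flags (`**` at 0.01, `*` at 0.05). Zero-variance traits give
#' NA rows.
#'
#' @param blups a `blup_result` or a data frame with a `line` column and one
#'   numeric column per trait.
#' @return list of class `trait_correlations` with matrices `r`, `p`, `sig`.
#' @export
trait_correlations <- function(blups) {
  b <- if (inherits(blups, "blup_result")) blups$blups else blups
  traits <- setdiff(names(b), "line")
  if (nrow(b) < 3) stop("need at least 3 lines")
  m <- as.matrix(b[traits])
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) >= 3 && stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
      ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  sig <- matrix("", k, k, dimnames = list(traits, traits))
  sig[!is.na(p) & p < 0.05] <- "*"
  sig[!is.na(p) & p < 0.01] <- "**"
  diag(sig) <- ""
  structure(list(r = r, p = p, sig = sig), class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  out <- matrix(paste0(format(round(x$r, digits)), x$sig),
                nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Weighted mean of additive effects (WAF)
#'
#' Combines per-trait additive effects of a block into one value using the
#' weights `r_t * H2_t`, where `r_t` is the (positive) correlation of trait
#' `t` with the anchor trait and `H2_t` its broad-sense heritability:
#' \deqn{WAF = \sum_t Add_t\, r_t H^2_t \Big/ \sum_t r_t H^2_t}
#' Traits with non-positive or missing `r` are excluded. For each block the
#' weighted mean runs over the traits with an additive-effect estimate there;
#' blocks with none are NA. Being a weighted mean, WAF always lies between the
#' smallest and largest contributing `Add_t`, is scale-equivariant in the
#' effects and invariant to rescaling all weights.
#'
#' @param add numeric matrix of additive effects, blocks x traits (NA where a
#'   block has no estimate for a trait), or a data frame with a `block`
#'   column.
#' @param r named numeric vector: correlation of each trait with the anchor.
#' @param h2 named numeric vector: broad-sense heritability of each trait.
#' @param blocks optional `block_set`; when given, the block intervals are
#'   attached so the result doubles as a genome track.
#' @return data frame of class `waf_report`: `block`, `waf`, `n_traits` and,
#'   with `blocks`, `chrom`, `start`, `end`. The weights used are in
#'   `attr(, "weights")`.
#' @examples
#' add <- matrix(c(1, 2), 1, dimnames = list("block1", c("t1", "t2")))
#' compute_waf(add, r = c(t1 = 0.5, t2 = 0.5), h2 = c(t1 = 0.8, t2 = 0.4))
#' # (1*0.4 + 2*0.2) / 0.6 = 1.3333
#' @export
compute_waf <- function(add, r, h2, blocks = NULL) {
  if (is.data.frame(add)) {
    ids <- add$block
    add <- as.matrix(add[setdiff(names(add), "block")])
    rownames(add) <- ids
  }
  traits <- colnames(add)
  if (is.null(traits)) stop("add must have trait column names")
  if (!all(traits %in% names(r)) || !all(traits %in% names(h2)))
    stop("r and h2 must be named for every trait in add")
  r <- r[traits]; h2 <- h2[traits]
  use <- !is.na(r) & r > 0 & !is.na(h2)
  if (!any(use)) {
    warning("no trait with positive correlation weight; WAF is NA")
    w <- rep(0, length(traits))
  } else w <- ifelse(use, r * h2, 0)
  if (all(w == 0) && any(use)) warning("all WAF weights are zero")
  W <- matrix(w, nrow(add), length(w), byrow = TRUE)
  W[is.na(add)] <- 0
  num <- rowSums(add * W, na.rm = TRUE)
  den <- rowSums(W)
  waf <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(block = rownames(add), waf = waf,
                    n_traits = rowSums(W > 0), stringsAsFactors = FALSE)
  if (!is.null(blocks)) {
    i <- match(out$block, blocks$blocks$block_id)
    out$chrom <- blocks$blocks$chrom[i]
    out$start <- blocks$blocks$start[i]
    out$end <- blocks$blocks$end[i]
  }
  rownames(out) <- NULL
  attr(out, "weights") <- stats::setNames(w, traits)
  class(out) <- c("waf_report", "data.frame")
  out
}
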