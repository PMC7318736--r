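#' Configuration for a synthetic CSSL population
#'
#' Describes the population a CSSL genotyping pipeline assumes: a recipient
#' (recurrent-parent) genome into which each line carries a small number of
#' donor segments, homozygous or heterozygous, observed through dense
#' biallelic SNPs and sparse SSR markers, both subject to genotyping error and
#' missingness. Defaults emulate an interspecific cotton CSSL panel scaled
#' down to a tractable genome: 26 chromosomes, 325 lines, 1-10 donor segments
#' per line, about 5 SNPs/kb between the parents, roughly 2 cM per Mb.
#'
#' @param chr_lengths numeric vector of chromosome lengths in bp. With 26
#'   chromosomes they are named A01..A13/D01..D13 and tagged with At/Dt
#'   subgenomes; otherwise chr01, chr02, ...
#' @param n_lines number of lines in the population.
#' @param segments_per_line integer vector `c(min, max)`: each line carries a
#'   uniform random number of donor segments in this range.
#' @param segment_length numeric vector `c(min, max)` in bp; lengths are drawn
#'   log-uniformly in this range (introgression lengths span orders of
#'   magnitude in real panels).
#' @param segment_gap minimum distance in bp between two planted segments of
#'   the same line on one chromosome. Independent introgressions in a CSSL
#'   panel derive from distinct recombination events and sit megabases apart;
#'   the separation also keeps the planted truth identifiable by any mapping
#'   method (two segments closer than a marker interval or the bin-merge
#'   distance are indistinguishable from one).
#' @param het_fraction probability that a planted segment is heterozygous.
#' @param snp_density expected SNPs per kb between the parents.
#' @param genotyping_error per-call probability that a genotype is replaced by
#'   one of the two other states.
#' @param missing_rate per-call probability that a genotype is missing.
#' @param marker_spacing mean distance between SSR markers in bp.
#' @param cm_per_mb genetic-to-physical scaling used to place marker cM
#'   positions and genetic chromosome lengths.
#' @param n_envs number of phenotyping environments.
#' @param seed integer seed; all simulation randomness is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chr_lengths = rep(20e6, 26),
                       n_lines = 325,
                       segments_per_line = c(1, 10),
                       segment_length = c(5e5, 5e6),
                       segment_gap = 2e6,
                       het_fraction = 0.05,
                       snp_density = 5,
                       genotyping_error = 0.01,
                       missing_rate = 0.05,
                       marker_spacing = 4e6,
                       cm_per_mb = 2,
                       n_envs = 5,
                       seed = 1L) {
  stopifnot(length(chr_lengths) >= 1, all(chr_lengths > 0),
            n_lines >= 1, n_envs >= 1,
            length(segments_per_line) == 2,
            segments_per_line[1] >= 1,
            segments_per_line[1] <= segments_per_line[2],
            length(segment_length) == 2,
            segment_length[1] > 0,
            segment_length[1] <= segment_length[2],
            segment_gap >= 0, marker_spacing > 0, cm_per_mb > 0)
  for (p in c(het_fraction, genotyping_error, missing_rate))
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!is.finite(snp_density) || snp_density <= 0)
    stop("snp_density must be positive")
  if (segment_length[2] > max(chr_lengths))
    stop("segment length exceeds every chromosome length")
  nm <- names(chr_lengths)
  if (is.null(nm)) {
    nm <- if (length(chr_lengths) == 26) {
      c(sprintf("A%02d", 1:13), sprintf("D%02d", 1:13))
    } else sprintf("chr%02d", seq_along(chr_lengths))
  }
  sub <- if (all(grepl("^[AD]", nm))) ifelse(grepl("^A", nm), "At", "Dt") else NULL
  cfg <- list(chr_lengths = stats::setNames(as.numeric(chr_lengths), nm),
              subgenome = sub,
              n_lines = as.integer(n_lines),
              segments_per_line = as.integer(segments_per_line),
              segment_length = as.numeric(segment_length),
              segment_gap = as.numeric(segment_gap),
              het_fraction = het_fraction,
              snp_density = snp_density,
              genotyping_error = genotyping_error,
              missing_rate = missing_rate,
              marker_spacing = marker_spacing,
              cm_per_mb = cm_per_mb,
              n_envs = as.integer(n_envs),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Genotype codes used throughout: 0 recipient-hom, 1 heterozygous, 2 donor-hom,
# NA missing.
GENO_RECIPIENT <- 0L
GENO_HET <- 1L
GENO_DONOR <- 2L

sim_genome <- function(config) {
  genome_map(names(config$chr_lengths),
             length_bp = config$chr_lengths,
             length_cm = config$chr_lengths / 1e6 * config$cm_per_mb,
             subgenome = config$subgenome)
}

# Place k non-overlapping segments on a line by rejection sampling.
place_line_segments <- function(config, line) {
  k <- if (config$segments_per_line[1] == config$segments_per_line[2])
    config$segments_per_line[1]
  else sample(config$segments_per_line[1]:config$segments_per_line[2], 1L)
  chroms <- names(config$chr_lengths)
  placed <- vector("list", k)
  for (s in seq_len(k)) {
    len <- exp(stats::runif(1, log(config$segment_length[1]),
                            log(config$segment_length[2])))
    len <- round(len)
    ok <- FALSE
    for (try in 1:100) {
      ci <- sample.int(length(chroms), 1L, prob = config$chr_lengths)
      clen <- config$chr_lengths[ci]
      if (len > clen) next
      start <- floor(stats::runif(1, 0, clen - len))
      end <- start + len
      prev <- placed[seq_len(s - 1L)]
      gap <- config$segment_gap
      clash <- any(vapply(prev, function(p) {
        !is.null(p) && p$chrom == chroms[ci] &&
          start < p$end + gap && p$start - gap < end
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a non-overlapping segment in 100 tries")
    placed[[s]] <- list(chrom = chroms[ci], start = start, end = end,
                        state = if (stats::runif(1) < config$het_fraction)
                          "het" else "donor")
  }
  data.frame(line = line,
             chrom = vapply(placed, `[[`, character(1), "chrom"),
             start = vapply(placed, `[[`, numeric(1), "start"),
             end = vapply(placed, `[[`, numeric(1), "end"),
             state = vapply(placed, `[[`, character(1), "state"),
             stringsAsFactors = FALSE)
}

# True genotype code of positions (0-based bp) on one chromosome for one line.
truth_codes <- function(segments, line, chrom, pos) {
  g <- rep(GENO_RECIPIENT, length(pos))
  segs <- segments[segments$line == line & segments$chrom == chrom, ,
                   drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    inside <- pos >= segs$start[i] & pos < segs$end[i]
    g[inside] <- if (segs$state[i] == "donor") GENO_DONOR else GENO_HET
  }
  g
}

# Apply genotyping error (replace by one of the two other codes, uniformly)
# then missingness.
corrupt_codes <- function(g, error, missing) {
  n <- length(g)
  if (error > 0) {
    hit <- stats::runif(n) < error
    if (any(hit)) {
      shift <- sample(1:2, sum(hit), replace = TRUE)
      g[hit] <- (g[hit] + shift) %% 3L
    }
  }
  if (missing > 0) g[stats::runif(n) < missing] <- NA_integer_
  g
}

#' Simulate a CSSL population with known ground truth
#'
#' Plants non-overlapping donor segments on each line, then derives per-line
#' SNP genotypes (donor allele inside homozygous-donor segments, heterozygous
#' calls inside heterozygous segments, recipient allele elsewhere) and SSR
#' marker graphical genotypes (DD/DR/RR) at sparse jittered-grid positions,
#' and finally corrupts both with the configured genotyping-error and
#' missing-data rates. The returned truth set drives parameter-recovery tests:
#' with error and missing rates of zero, emitted genotypes and planted
#' segments are mutually consistent by construction.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_population` with elements `snp` (a
#'   [snp_table()]), `markers` (a [marker_table()]), `truth` (list with the
#'   planted `segments` data frame and the `config`), and `genome` (a
#'   [genome_map()]).
#' @examples
#' pop <- simulate_population(sim_config(chr_lengths = c(A01 = 5e6),
#'   n_lines = 4, segments_per_line = c(1, 2), segment_length = c(5e5, 2e6),
#'   seed = 42))
#' head(pop$truth$segments)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  genome <- sim_genome(config)
  lines <- sprintf("L%03d", seq_len(config$n_lines))

  segments <- do.call(rbind, lapply(lines, function(l)
    place_line_segments(config, l)))
  rownames(segments) <- NULL

  # SNP scaffold: Poisson number of sites per chromosome, uniform positions.
  snp_list <- lapply(seq_len(nrow(genome)), function(ci) {
    len <- genome$length_bp[ci]
    n <- max(1L, stats::rpois(1, len / 1000 * config$snp_density))
    pos <- sort(sample.int(len, min(n, len)) - 1L)
    data.frame(chrom = genome$chrom[ci], pos = pos, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snp_list)
  base <- c("A", "C", "G", "T")
  snps$recipient_allele <- sample(base, nrow(snps), replace = TRUE)
  snps$donor_allele <- vapply(snps$recipient_allele,
                              function(r) sample(setdiff(base, r), 1L),
                              character(1))

  geno <- matrix(NA_integer_, nrow = nrow(snps), ncol = length(lines),
                 dimnames = list(NULL, lines))
  for (l in lines) {
    g <- unlist(lapply(genome$chrom, function(ch) {
      truth_codes(segments, l, ch, snps$pos[snps$chrom == ch])
    }), use.names = FALSE)
    geno[, l] <- corrupt_codes(g, config$genotyping_error, config$missing_rate)
  }
  snp <- snp_table(snps, geno)

  # SSR markers on a jittered grid; same truth and corruption model.
  mk_list <- lapply(seq_len(nrow(genome)), function(ci) {
    len <- genome$length_bp[ci]
    if (config$marker_spacing / 2 >= len)
      return(data.frame(marker = character(0), chrom = character(0),
                        bp = numeric(0), cm = numeric(0)))
    grid <- seq(config$marker_spacing / 2, len - 1, by = config$marker_spacing)
    pos <- grid + stats::runif(length(grid), -0.25, 0.25) * config$marker_spacing
    pos <- sort(pmin(pmax(round(pos), 0), len - 1))
    data.frame(marker = sprintf("S%s_%02d", genome$chrom[ci], seq_along(pos)),
               chrom = genome$chrom[ci], bp = pos,
               cm = pos / 1e6 * config$cm_per_mb, stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, mk_list)
  calls <- matrix(NA_character_, nrow = nrow(mk), ncol = length(lines),
                  dimnames = list(mk$marker, lines))
  code_chr <- c("RR", "DR", "DD")
  for (l in lines) {
    g <- unlist(lapply(genome$chrom, function(ch) {
      truth_codes(segments, l, ch, mk$bp[mk$chrom == ch])
    }), use.names = FALSE)
    g <- corrupt_codes(g, config$genotyping_error, config$missing_rate)
    calls[, l] <- ifelse(is.na(g), NA_character_, code_chr[g + 1L])
  }
  markers <- marker_table(mk, calls)

  out <- list(snp = snp, markers = markers,
              truth = list(segments = segments, config = config),
              genome = genome)
  class(out) <- "sim_population"
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "sim_population: %d lines, %d chromosomes, %d SNPs, %d markers, %d planted segments\n",
    x$truth$config$n_lines, nrow(x$genome), nrow(x$snp$snps),
    nrow(x$markers$markers), nrow(x$truth$segments)))
  invisible(x)
}

#' Simulate multi-environment phenotypes over a block partition
#'
#' Generates phenotype records under the additive model
#' \deqn{y_{ij} = \mu + env_j + \sum_b 2 a_b x_{ib} + g_i + e_{ij}}
#' where `x` is the donor dosage (0 recipient, 0.5 heterozygous, 1
#' donor-homozygous), so the fitted additive effect `a` is half the difference
#' between the two homozygous classes, `g_i ~ N(0, sigma2_g)` is a polygenic
#' line effect and `e_ij ~ N(0, sigma2_e)` is residual noise. Environment
#' effects are fixed offsets, drawn once from `N(0, env_sd^2)` unless supplied.
#'
#' @param truth truth list from [simulate_population()] (used for its config;
#'   the QTL planted here are appended to it by the caller if desired).
#' @param blocks a `block_set` from [partition_blocks()].
#' @param qtl data frame with columns `block`, `trait`, `a` (additive effect in
#'   trait units); NULL plants no QTL.
#' @param traits character vector of trait names to generate (traits without a
#'   planted QTL are pure noise).
#' @param mu grand mean.
#' @param sigma2_g,sigma2_e polygenic and residual variance components.
#' @param env_effects optional numeric vector of fixed environment offsets
#'   (length `n_envs`); drawn from `N(0, env_sd^2)` when NULL.
#' @param env_sd standard deviation used to draw environment offsets.
#' @param n_envs number of environments; defaults to the config value.
#' @param seed integer seed.
#' @return A long-format data frame (`line`, `env`, `trait`, `value`) with the
#'   planted QTL, variance components and environment effects in attributes
#'   `qtl`, `varcomp` and `env_effects`.
#' @export
simulate_phenotypes <- function(truth, blocks, qtl = NULL,
                                traits = if (is.null(qtl)) "trait1"
                                         else unique(qtl$trait),
                                mu = 0, sigma2_g = 1, sigma2_e = 1,
                                env_effects = NULL, env_sd = 1,
                                n_envs = truth$config$n_envs, seed = 1L) {
  if (!inherits(blocks, "block_set")) stop("blocks must be a block_set")
  if (!is.null(qtl)) {
    bad <- setdiff(qtl$block, blocks$blocks$block_id)
    if (length(bad))
      stop(sprintf("unknown block id(s): %s", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  lines <- blocks$lines
  n <- length(lines)
  envs <- sprintf("E%d", seq_len(n_envs))
  if (is.null(env_effects)) env_effects <- stats::rnorm(n_envs, 0, env_sd)
  if (length(env_effects) != n_envs) stop("env_effects must have length n_envs")

  recs <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    gval <- rep(mu, n)
    if (!is.null(qtl)) {
      qt <- qtl[qtl$trait == tr, , drop = FALSE]
      for (i in seq_len(nrow(qt))) {
        x <- blocks$dosage[, qt$block[i]]
        gval <- gval + 2 * qt$a[i] * x
      }
    }
    gline <- gval + stats::rnorm(n, 0, sqrt(sigma2_g))
    e <- matrix(stats::rnorm(n * n_envs, 0, sqrt(sigma2_e)), n, n_envs)
    y <- outer(gline, env_effects, `+`) + e
    recs[[ti]] <- data.frame(line = rep(lines, times = n_envs),
                             env = rep(envs, each = n),
                             trait = tr,
                             value = as.vector(y),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  attr(out, "qtl") <- qtl
  attr(out, "varcomp") <- c(sigma2_g = sigma2_g, sigma2_e = sigma2_e)
  attr(out, "env_effects") <- stats::setNames(env_effects, envs)
  out
}
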