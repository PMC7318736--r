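# File I/O: genome table, SNP genotypes (VCF and allele-matrix TSV), SSR
# marker tables, segments/bins/blocks as BED-like TSV, phenotypes as CSV, and
# the end-to-end pipeline driver with its JSON manifest.

snp_code_chr <- c(`0` = "R", `1` = "H", `2` = "D")

#' Read a genome table
#'
#' TSV with columns `chrom`, `length_bp` and optionally `length_cm`,
#' `subgenome`.
#' @param path file path.
#' @return a [genome_map()].
#' @export
read_genome <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_map(d$chrom, d$length_bp, d$length_cm, d$subgenome)
}

#' Read SNP genotypes from a VCF
#'
#' Biallelic sites only; multi-allelic sites and sites where either parent is
#' missing or heterozygous are dropped (counts reported). Line calls are
#' classified against the parental genotypes; calls carrying a non-parental
#' allele become missing. Positions are converted to the package's 0-based
#' convention and sorted if needed.
#'
#' @param path VCF file (plain or bgzipped).
#' @param donor,recipient sample names of the two parents in the VCF.
#' @return a [snp_table()] of the non-parent samples.
#' @export
read_snp_vcf <- function(path, donor, recipient) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(c(donor, recipient) %in% samples))
    stop(sprintf("parent sample(s) not in VCF: %s",
                 paste(setdiff(c(donor, recipient), samples), collapse = ", ")))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  if (any(multi))
    message(sprintf("read_snp_vcf: dropped %d multi-allelic/ALT-less site(s)",
                    sum(multi)))
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  # translate numeric GT to allele strings
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  to_allele <- function(g) {
    a <- matrix(NA_character_, length(g), 2)
    sp <- strsplit(g, "[/|]")
    for (i in seq_along(sp)) {
      v2 <- sp[[i]]
      if (length(v2) == 2 && !any(v2 == ".") && !anyNA(v2)) {
        idx <- as.integer(v2)
        a[i, ] <- ifelse(idx == 0, ref[i], alt[i])
      }
    }
    paste(a[, 1], a[, 2], sep = "/")
  }
  gta <- apply(gt, 2, to_allele)
  gta[grepl("NA", gta)] <- NA_character_
  pos <- as.numeric(fix[, "POS"]) - 1  # VCF is 1-based
  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                      donor_gt = gta[, donor], recipient_gt = gta[, recipient],
                      stringsAsFactors = FALSE)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (any(ord != seq_along(ord))) {
    warning("VCF positions unsorted; sorting")
    sites <- sites[ord, , drop = FALSE]
    gta <- gta[ord, , drop = FALSE]
  }
  prog <- setdiff(samples, c(donor, recipient))
  filter_alleles(gta[, prog, drop = FALSE], sites)
}

#' Write a SNP table as a minimal VCF
#'
#' The recipient allele is written as REF (the recipient is the reference
#' background), the donor allele as ALT; genotypes are `0/0`, `0/1`, `1/1` or
#' `./.`. The two parent columns are emitted first with their defining
#' genotypes.
#'
#' @param tab a [snp_table()] with allele columns.
#' @param path output path.
#' @param genome optional [genome_map()] for contig headers.
#' @param donor,recipient parent sample names to write.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(tab, path, genome = NULL,
                          donor = "donor", recipient = "recipient") {
  if (is.null(tab$snps$donor_allele))
    stop("snp table has no allele columns")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                          as.integer(genome$length_bp)))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donor, recipient, tab$lines)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- matrix("", nrow(tab$snps), length(cols))
  body[, 1] <- tab$snps$chrom
  body[, 2] <- format(tab$snps$pos + 1, scientific = FALSE, trim = TRUE)
  body[, 3] <- "."
  body[, 4] <- tab$snps$recipient_allele
  body[, 5] <- tab$snps$donor_allele
  body[, 6] <- "."; body[, 7] <- "PASS"; body[, 8] <- "."; body[, 9] <- "GT"
  body[, 10] <- "1/1"  # donor parent
  body[, 11] <- "0/0"  # recipient parent
  g <- tab$geno
  body[, 12:length(cols)] <- ifelse(is.na(g), "./.", gt_map[as.character(g)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write / read a SNP table as TSV
#'
#' Columns `chrom`, `pos` (0-based), `donor_allele`, `recipient_allele`, then
#' one column per line with calls `D` (donor-hom), `H` (het), `R`
#' (recipient-hom) or `.` (missing).
#' @param tab a [snp_table()].
#' @param path file path.
#' @return `write_snp_tsv`: `path` invisibly; `read_snp_tsv`: a [snp_table()].
#' @export
write_snp_tsv <- function(tab, path) {
  g <- tab$geno
  chr <- ifelse(is.na(g), ".", snp_code_chr[as.character(g)])
  d <- cbind(tab$snps, as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_tsv
#' @export
read_snp_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  meta_cols <- intersect(c("chrom", "pos", "donor_allele", "recipient_allele"),
                         names(d))
  lines <- setdiff(names(d), meta_cols)
  code <- c(R = 0L, H = 1L, D = 2L)
  g <- vapply(lines, function(l) unname(code[d[[l]]]), integer(nrow(d)))
  if (!is.matrix(g)) g <- matrix(g, nrow = nrow(d), dimnames = list(NULL, lines))
  snps <- data.frame(chrom = d$chrom, pos = as.numeric(d$pos),
                     stringsAsFactors = FALSE)
  if ("donor_allele" %in% meta_cols) {
    snps$donor_allele <- d$donor_allele
    snps$recipient_allele <- d$recipient_allele
  }
  snp_table(snps, g)
}

#' Write / read an SSR marker table as TSV
#'
#' Columns `marker`, `chrom`, `cm`, `bp`, then one column per line with
#' `DD`/`DR`/`RR`/`NA`.
#' @param table a [marker_table()].
#' @param path file path.
#' @return `write_marker_tsv`: `path` invisibly; `read_marker_tsv`: a
#'   [marker_table()].
#' @export
write_marker_tsv <- function(table, path) {
  d <- cbind(table$markers, as.data.frame(table$calls,
                                          stringsAsFactors = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("marker", "chrom", "cm", "bp"), names(d))
  lines <- setdiff(names(d), meta_cols)
  calls <- as.matrix(d[lines])
  rownames(calls) <- d$marker
  marker_table(d[meta_cols], calls)
}

#' Write intervals as BED-like TSV
#'
#' 0-based half-open, sorted by chromosome then start; works for segments,
#' bins and blocks (any data frame with `chrom`, `start`, `end`).
#' @param x interval data frame.
#' @param path file path.
#' @param genome optional [genome_map()] fixing chromosome sort order.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, genome = NULL) {
  ord <- if (!is.null(genome)) order(match(x$chrom, genome$chrom), x$start)
         else order(x$chrom, x$start)
  x <- x[ord, , drop = FALSE]
  first <- c("chrom", "start", "end")
  x <- x[c(first, setdiff(names(x), first))]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a long-format phenotype CSV
#'
#' Columns `line`, `env`, `trait`, `value` (extra columns such as `rep` are
#' carried along).
#' @param pheno phenotype data frame.
#' @param path file path.
#' @return `read_phenotypes`: the data frame; `write_phenotypes`: `path`
#'   invisibly.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "env", "trait", "value") %in% names(d)))
  d$value <- as.numeric(d$value)
  d
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation truth set
#'
#' Planted segments as BED-like TSV plus a JSON sidecar with the simulation
#' configuration (and, when supplied, planted QTL and variance components).
#' @param truth truth list from [simulate_population()].
#' @param prefix output path prefix; writes `<prefix>_segments.tsv` and
#'   `<prefix>.json`.
#' @param qtl optional planted-QTL data frame (from the `qtl` attribute of
#'   [simulate_phenotypes()] output).
#' @param varcomp optional named variance-component vector.
#' @return the two paths, invisibly.
#' @export
write_truth <- function(truth, prefix, qtl = NULL, varcomp = NULL) {
  seg_path <- paste0(prefix, "_segments.tsv")
  json_path <- paste0(prefix, ".json")
  write_bed(truth$segments, seg_path)
  side <- list(config = unclass(truth$config), qtl = qtl,
               varcomp = as.list(varcomp))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(seg_path, json_path))
}

#' Run the full CSSL dissection pipeline
#'
#' Orchestrates the stages on file inputs: marker map (SSR segments +
#' summary), sequencing map (bin map + segments), coverage report, BLUP/H2,
#' trait correlations, block partition, QTL scan and WAF, writing each
#' artifact plus a JSON manifest (input hashes, parameters, package version).
#' Stages without inputs are skipped with a notice; a stage failure aborts
#' with the stage name, preserving earlier outputs.
#'
#' @param config list (or path to a JSON file) with elements: `genome` (path),
#'   optional `markers`, `snps` (TSV or VCF; VCF needs `donor`/`recipient`
#'   sample names), `phenotypes`; `out_dir`; optional `bin_params` (list),
#'   `qtl` (list: `p_in`, `p_out`, `lod_threshold`, `sign_flip`), `waf`
#'   (list: `anchor` trait), `seed`.
#' @return list of produced objects (invisibly also written under `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$genome) || is.null(config$out_dir))
    stop("config needs at least genome and out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outf <- function(f) file.path(config$out_dir, f)
  res <- list()
  inputs <- c(genome = config$genome, markers = config$markers,
              snps = config$snps, phenotypes = config$phenotypes)

  genome <- stage("genome", read_genome(config$genome))
  res$genome <- genome

  if (!is.null(config$markers)) {
    res$mm_segments <- stage("mm-map", {
      mt <- read_marker_tsv(config$markers)
      segs <- call_marker_segments(mt, genome,
                                   unit = if (!is.null(mt$markers$cm)) "cm"
                                          else "bp")
      utils::write.table(segs, outf("mm_segments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(mm_summary(segs, genome), outf("mm_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      segs
    })
    res$mm_coverage <- stage("mm-coverage", {
      cov <- union_coverage(res$mm_segments, genome,
                            unit = attr(res$mm_segments, "unit"))
      utils::write.table(cov, outf("mm_coverage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cov
    })
  } else message("run_pipeline: no marker input; MM-map stages skipped")

  if (!is.null(config$snps)) {
    res$gr <- stage("gr-map", {
      tab <- if (grepl("\\.vcf(\\.gz)?$", config$snps))
        read_snp_vcf(config$snps, config$donor, config$recipient)
      else read_snp_tsv(config$snps)
      params <- do.call(bin_params, as.list(config$bin_params))
      gr <- gr_map(tab, genome, params)
      write_bed(gr$bins, outf("bins.tsv"), genome)
      write_bed(gr$segments, outf("gr_segments.tsv"), genome)
      gr
    })
    res$gr_coverage <- stage("gr-coverage", {
      cov <- union_coverage(res$gr$segments, genome, unit = "bp")
      cov$fold_coverage <- c(rep(NA, nrow(cov) - 1),
                             fold_coverage(res$gr$segments, genome))
      utils::write.table(cov, outf("gr_coverage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cov
    })
  } else message("run_pipeline: no SNP input; GR-map stages skipped")

  if (!is.null(config$phenotypes) && !is.null(res$gr)) {
    res$blup <- stage("blup", {
      ph <- read_phenotypes(config$phenotypes)
      b <- fit_blup(ph)
      utils::write.csv(b$blups, outf("blups.csv"), row.names = FALSE)
      utils::write.csv(b$varcomp, outf("heritability.csv"), row.names = FALSE)
      b
    })
    res$correlations <- stage("correlations", {
      ct <- trait_correlations(res$blup)
      utils::write.csv(
        matrix(paste0(format(round(ct$r, 3)), ct$sig), nrow(ct$r),
               dimnames = dimnames(ct$r)), outf("correlations.csv"))
      ct
    })
    res$blocks <- stage("blocks", {
      bs <- partition_blocks(res$gr$segments, genome,
                             lines = union(unique(res$gr$bins$line),
                                           res$blup$blups$line))
      write_bed(bs$blocks, outf("blocks.tsv"), genome)
      utils::write.table(cbind(line = rownames(bs$dosage),
                               as.data.frame(bs$dosage)),
                         outf("block_dosage.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      bs
    })
    res$qtl <- stage("qtl", {
      q <- do.call(scan_qtl, c(list(blocks = res$blocks,
                                    blups = res$blup$blups),
                               as.list(config$qtl)))
      utils::write.table(q, outf("qtl.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      q
    })
    res$waf <- stage("waf", {
      traits <- setdiff(names(res$blup$blups), "line")
      anchor <- config$waf$anchor
      if (is.null(anchor)) anchor <- traits[1]
      r <- res$correlations$r[anchor, ]
      h2 <- stats::setNames(res$blup$varcomp$h2, res$blup$varcomp$trait)
      add <- matrix(NA_real_, nrow(res$blocks$blocks), length(traits),
                    dimnames = list(res$blocks$blocks$block_id, traits))
      for (i in seq_len(nrow(res$qtl)))
        add[res$qtl$block[i], res$qtl$trait[i]] <- res$qtl$add_effect[i]
      w <- compute_waf(add, r, h2, blocks = res$blocks)
      utils::write.table(w, outf("waf.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      w
    })
  } else if (!is.null(config$phenotypes)) {
    message("run_pipeline: phenotypes given but no SNP segments; QTL stages skipped")
  } else {
    message("run_pipeline: no phenotype input; QTL stages skipped")
  }

  manifest <- list(
    package = "cssltools",
    version = as.character(utils::packageVersion("cssltools")),
    inputs = as.list(tools::md5sum(inputs[!is.na(inputs)])),
    parameters = config[setdiff(names(config),
                                c("genome", "markers", "snps", "phenotypes",
                                  "out_dir"))],
    outputs = as.list(tools::md5sum(
      list.files(config$out_dir, full.names = TRUE,
                 pattern = "\\.(tsv|csv)$"))))
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}
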