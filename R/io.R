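# Tab-separated readers/writers for summary statistics, weights, phenotypes
# and allele-frequency panels, plus a minimal VCF bridge for genotype and
# haplotype matrices.

#' Write GWAS summary statistics to a tab-separated file
#'
#' Floats are written at 6 significant digits, p-values in scientific
#' notation.
#'
#' @param stats A `variant_stats` data frame.
#' @param path Output path.
#' @export
write_sumstats <- function(stats, path) {
  out <- as.data.frame(stats)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "pos"
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  if ("p" %in% names(out)) out$p <- format(out$p, scientific = TRUE, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Requires a header. Two effect dialects are auto-detected from column
#' names: a log-odds dialect (`beta` + `se`) is read as-is; an odds-ratio
#' dialect (`or` + `ci_low` + `ci_high`) is converted to `beta`/`se` on load
#' via the 95% Wald back-calculation of [ci_to_se()].
#'
#' @param path Input path.
#' @return A `variant_stats` data frame.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"snp" %in% names(tab)) stop("summary-statistic file must have a `snp` column")
  if (!"beta" %in% names(tab)) {
    if (all(c("or", "ci_low", "ci_high") %in% names(tab))) {
      z <- stats::qnorm(0.975)
      tab$beta <- log(tab$or)
      tab$se <- log(tab$ci_high / tab$ci_low) / (2 * z)
      tab$or <- tab$ci_low <- tab$ci_high <- NULL
    } else {
      stop("expected either `beta`+`se` or `or`+`ci_low`+`ci_high` columns")
    }
  }
  if ("p" %in% names(tab)) tab$p <- as.numeric(tab$p)
  class(tab) <- c("variant_stats", "data.frame")
  tab
}

#' Read an allele-score weight file
#'
#' Tab-separated with header columns `trait`, `snp`, `ea`, `oa`,
#' `weight_sd_per_allele` and optionally `eaf` and `source`.
#'
#' @param path Input path.
#' @param trait Trait to extract (default: the file's single trait).
#' @return A [score_definition()].
#' @export
read_weights <- function(path, trait = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(trait)) {
    trait <- unique(tab$trait)
    if (length(trait) != 1L) stop("file holds several traits; name one")
  }
  tab <- tab[tab$trait == trait, , drop = FALSE]
  snps <- data.frame(snp = tab$snp, ea = tab$ea, oa = tab$oa,
                     weight = tab$weight_sd_per_allele,
                     stringsAsFactors = FALSE)
  if ("eaf" %in% names(tab)) snps$eaf <- tab$eaf
  score_definition(trait, snps)
}

#' Write a phenotype/exposure table
#'
#' @param data Data frame (e.g. id, exposure, outcome, covariates).
#' @param path Output path.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an allele-frequency panel as a tab-separated table
#'
#' One row per population; first column `population`, then one column per
#' SNP.
#'
#' @param panel A [pop_freq_panel()].
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "pop_freq_panel"))
  out <- data.frame(population = rownames(panel$freqs),
                    n_haplotypes = panel$sample_sizes,
                    signif(panel$freqs, 6), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency panel written by [write_panel()]
#'
#' @param path Input path.
#' @return A [pop_freq_panel()].
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  freqs <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(freqs) <- tab$population
  pop_freq_panel(freqs, sample_sizes = tab$n_haplotypes)
}

#' Write genotype dosages or phased haplotypes as VCF
#'
#' Diploid dosage matrices (entries 0/1/2) are written as unphased GT fields
#' (`0/0`, `0/1`, `1/1`); [haplotype_matrix()] inputs are written phased,
#' pairing consecutive haplotypes into individuals and recording the
#' ancestral allele in the `AA` INFO tag.
#'
#' @param x Dosage matrix (individuals x SNPs) or a [haplotype_matrix()].
#' @param path Output path.
#' @param chrom Chromosome label for all sites.
#' @param pos Positions (defaults to `hap$positions` or 1..m).
#' @param ref,alt Reference (ancestral) and alternate (derived/effect)
#'   alleles per site.
#' @export
write_vcf <- function(x, path, chrom = "1", pos = NULL,
                      ref = NULL, alt = NULL) {
  phased <- inherits(x, "haplotype_matrix")
  if (phased) {
    mat <- x$haplotypes
    if (nrow(mat) %% 2L == 1L) mat <- mat[-nrow(mat), , drop = FALSE]
    pos <- pos %||% x$positions
  } else {
    mat <- as.matrix(x)
    pos <- pos %||% seq_len(ncol(mat))
  }
  m <- ncol(mat)
  ref <- ref %||% rep("A", m)
  alt <- alt %||% rep("G", m)
  ids <- colnames(mat) %||% paste0("snp", seq_len(m))
  gt <- if (phased) {
    odd <- seq(1L, nrow(mat), by = 2L)
    sapply(seq_len(m), function(j)
      paste0(mat[odd, j], "|", mat[odd + 1L, j]))
  } else {
    sapply(seq_len(m), function(j)
      c("0/0", "0/1", "1/1")[mat[, j] + 1L])
  }
  gt <- matrix(gt, ncol = m)
  info <- if (phased) paste0("AA=", ref) else "."
  body <- cbind(chrom, pos, ids, ref, alt, ".", "PASS", info, "GT", t(gt))
  n_ind <- nrow(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", seq_len(n_ind))), collapse = "\t"))
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix or haplotype matrix
#'
#' Uses vcfR for parsing. With `as = "dosage"` the ALT-allele dosage matrix
#' (individuals x SNPs) is returned; with `as = "haplotypes"` phased GT
#' fields are split into a [haplotype_matrix()], polarised by the `AA` INFO
#' tag when present (sites whose ancestral allele equals ALT are flipped).
#'
#' @param path VCF path.
#' @param as `"dosage"` or `"haplotypes"`.
#' @return Dosage matrix or [haplotype_matrix()].
#' @export
read_vcf <- function(path, as = c("dosage", "haplotypes")) {
  as <- match.arg(as)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.numeric(vcfR::getPOS(v))
  ids <- vcfR::getID(v)
  if (as == "dosage") {
    dose <- t(matrix(vapply(strsplit(gt, "[|/]"), function(a)
      sum(as.integer(a)), numeric(1)), nrow = nrow(gt)))
    colnames(dose) <- ids
    return(dose)
  }
  split_gt <- strsplit(gt, "|", fixed = TRUE)
  halves <- vapply(split_gt, function(a) as.integer(a[c(1L, 2L)]),
                   integer(2))
  n_sites <- nrow(gt)
  n_ind <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = n_sites)
  hm <- matrix(halves, nrow = 2L)
  for (j in seq_len(n_sites)) {
    cols <- ((seq_len(n_ind) - 1L) * n_sites) + j
    hap[seq(1L, 2L * n_ind, 2L), j] <- hm[1L, cols]
    hap[seq(2L, 2L * n_ind, 2L), j] <- hm[2L, cols]
  }
  info_aa <- vcfR::extract.info(v, element = "AA")
  alt <- vcfR::getALT(v)
  flip <- !is.na(info_aa) & info_aa == alt
  hap[, flip] <- 1L - hap[, flip]
  ord <- order(pos)
  haplotype_matrix(hap[, ord, drop = FALSE], pos[ord])
}

#' Harmonize two summary-statistic tables
#'
#' Aligns table `b` to table `a` on shared variant ids: direct allele
#' matches (including strand complements) are kept; allele-swapped matches
#' have their `beta` negated and `eaf` complemented; palindromic variants
#' needing a swap, and variants matching neither orientation, are dropped.
#'
#' @param stats_a,stats_b `variant_stats` data frames with columns `snp`,
#'   `ea`, `oa`, `beta` (and optionally `eaf`); ids must be unique within
#'   each table.
#' @return A list with the aligned `a` and `b` tables (same row order) and
#'   `dropped`, the ids removed as unresolvable.
#' @export
harmonize <- function(stats_a, stats_b) {
  for (tab in list(stats_a, stats_b)) {
    if (anyDuplicated(tab$snp)) stop("duplicate variant ids within one table")
  }
  shared <- intersect(stats_a$snp, stats_b$snp)
  a <- stats_a[match(shared, stats_a$snp), , drop = FALSE]
  b <- stats_b[match(shared, stats_b$snp), , drop = FALSE]
  act <- resolve_orientation(a$ea, a$oa, b$ea, b$oa,
                             w_eaf = a$eaf %||% NULL,
                             g_eaf = b$eaf %||% NULL)
  keep <- act != "drop"
  dropped <- shared[!keep]
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  flip <- act[keep] == "flip"
  b$beta[flip] <- -b$beta[flip]
  if (!is.null(b$eaf)) b$eaf[flip] <- 1 - b$eaf[flip]
  b$ea <- a$ea
  b$oa <- a$oa
  rownames(a) <- rownames(b) <- NULL
  list(a = a, b = b, dropped = dropped)
}

#' Greedy lead-SNP selection and significance tiers
#'
#' Selects lead SNPs greedily by ascending p-value, suppressing every other
#' SNP within `window / 2` bases of a chosen lead on the same chromosome
#' (so "one signal per 1-Mb window" by default), and labels each lead by the
#' significance tier its p-value reaches: `genome_wide` (p < 1e-8),
#' `significant` (p < 5e-8), `suggestive` (p < 1e-6), `possible` (p < 1e-5)
#' or `none`.
#'
#' @param stats Data frame with `snp`, `chr`, `pos`, `p`.
#' @param window Signal window width in bases (default 1 Mb, i.e. +/-500 kb
#'   around each lead).
#' @param tiers Named vector of tier thresholds, most stringent first.
#' @return The input restricted to lead SNPs, with a `tier` column, ordered
#'   by p-value.
#' @export
signal_tiers <- function(stats, window = 1e6,
                         tiers = c(genome_wide = 1e-8, significant = 5e-8,
                                   suggestive = 1e-6, possible = 1e-5)) {
  if (nrow(stats) == 0L) {
    out <- stats
    out$tier <- character(0)
    return(out)
  }
  ord <- order(stats$p)
  suppressed <- rep(FALSE, nrow(stats))
  lead <- logical(nrow(stats))
  half <- window / 2
  for (i in ord) {
    if (suppressed[i]) next
    lead[i] <- TRUE
    suppressed <- suppressed |
      (stats$chr == stats$chr[i] & abs(stats$pos - stats$pos[i]) <= half)
  }
  out <- stats[lead, , drop = FALSE]
  out$tier <- vapply(out$p, function(p) {
    hit <- names(tiers)[p < tiers]
    if (length(hit)) hit[1L] else "none"
  }, character(1))
  out[order(out$p), , drop = FALSE]
}
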