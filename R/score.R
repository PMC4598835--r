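#' Define a weighted multiple allele score
#'
#' A score definition names, for one exposure trait, the instrument SNPs with
#' their effect/other alleles and per-allele weights in exposure
#' standard-deviation units, plus the calibration constant converting one raw
#' score unit into exposure standard deviations.
#'
#' @param trait Exposure trait label.
#' @param snps Data frame with columns `snp`, `ea`, `oa`, `weight`
#'   (s.d. of exposure per effect allele) and optionally `eaf` (effect-allele
#'   frequency, used to resolve palindromic SNPs).
#' @param calibration Exposure s.d. per raw score unit (> 0). With weights
#'   equal to the true per-allele effects the raw score is already on the
#'   s.d. scale and the calibration is 1.
#' @return A `score_definition` object.
#' @export
score_definition <- function(trait, snps, calibration = 1) {
  stopifnot(is.data.frame(snps),
            all(c("snp", "ea", "oa", "weight") %in% names(snps)))
  if (anyDuplicated(snps$snp)) stop("duplicated variant ids in score")
  if (!all(is.finite(snps$weight))) stop("weights must be finite")
  if (!is.finite(calibration) || calibration <= 0) {
    stop("`calibration` must be positive")
  }
  structure(list(trait = trait, snps = snps, calibration = calibration),
            class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Allele score for '%s': %d SNPs, calibration %.4g s.d./unit\n",
              x$trait, nrow(x$snps), x$calibration))
  invisible(x)
}

# Resolve the orientation of each score SNP against genotype allele labels.
# Returns per-SNP action: "as_is", "flip" (dose -> 2 - dose) or "drop".
resolve_orientation <- function(w_ea, w_oa, g_ea, g_oa,
                                w_eaf = NULL, g_eaf = NULL,
                                palindromic_eaf_margin = 0.08) {
  w_ea <- toupper(w_ea); w_oa <- toupper(w_oa)
  g_ea <- toupper(g_ea); g_oa <- toupper(g_oa)
  n <- length(w_ea)
  act <- rep("drop", n)
  pal <- is_palindromic(w_ea, w_oa)
  direct <- (g_ea == w_ea & g_oa == w_oa) |
    (g_ea == allele_complement(w_ea) & g_oa == allele_complement(w_oa))
  swapped <- (g_ea == w_oa & g_oa == w_ea) |
    (g_ea == allele_complement(w_oa) & g_oa == allele_complement(w_ea))
  act[direct & !pal] <- "as_is"
  act[swapped & !pal] <- "flip"
  # palindromic SNPs: strand is unknowable from the letters; align by allele
  # frequency when it is informative, otherwise drop
  if (any(pal)) {
    if (!is.null(w_eaf) && !is.null(g_eaf)) {
      informative <- pal & (direct | swapped) &
        abs(w_eaf - 0.5) > palindromic_eaf_margin &
        abs(g_eaf - 0.5) > palindromic_eaf_margin
      same_side <- sign(w_eaf - 0.5) == sign(g_eaf - 0.5)
      act[informative & same_side] <- "as_is"
      act[informative & !same_side] <- "flip"
    }
    n_drop <- sum(pal & (direct | swapped) & act == "drop")
    if (n_drop > 0) {
      warning(sprintf("%d palindromic SNP(s) dropped (frequency uninformative)",
                      n_drop))
    }
  }
  act
}

#' Compute per-individual raw allele scores
#'
#' The raw score of individual *i* is `sum_j weight_j * dose_ij` over the
#' score SNPs, after harmonizing the genotype dosage to the score's effect
#' allele (direct match or strand complement kept as-is; allele-swapped
#' matches replaced by `2 - dose`; palindromic SNPs resolved by allele
#' frequency when both frequencies are at least 0.08 from 0.5, else dropped).
#' Missing dosages are mean-imputed from the sample allele frequency. SNPs
#' whose alleles resolve to neither orientation are dropped with a warning.
#'
#' @param weights A [score_definition()].
#' @param genotypes Individuals x SNPs dosage matrix with SNP ids as column
#'   names (dosages count `geno_alleles$ea`).
#' @param geno_alleles Optional data frame (`snp`, `ea`, `oa`) describing the
#'   allele counted by each genotype column; when absent, dosages are assumed
#'   already aligned with the score's effect alleles.
#' @return Numeric vector of raw scores with attribute `n_snps_used`.
#' @export
build_score <- function(weights, genotypes, geno_alleles = NULL) {
  stopifnot(inherits(weights, "score_definition"))
  genotypes <- as.matrix(genotypes)
  tab <- weights$snps
  idx <- match(tab$snp, colnames(genotypes))
  if (anyNA(idx)) {
    stop(sprintf("score SNP(s) missing from genotypes: %s",
                 paste(tab$snp[is.na(idx)], collapse = ", ")))
  }
  dose <- if (identical(idx, seq_len(ncol(genotypes)))) genotypes else
    genotypes[, idx, drop = FALSE]
  g_eaf <- colMeans(dose, na.rm = TRUE) / 2
  if (!is.null(geno_alleles)) {
    gi <- match(tab$snp, geno_alleles$snp)
    act <- resolve_orientation(tab$ea, tab$oa,
                               geno_alleles$ea[gi], geno_alleles$oa[gi],
                               w_eaf = tab$eaf %||% NULL, g_eaf = g_eaf)
  } else {
    act <- rep("as_is", nrow(tab))
  }
  if (any(act == "drop" & !is_palindromic(tab$ea, tab$oa))) {
    warning(sprintf("%d SNP(s) dropped: unresolvable allele mismatch",
                    sum(act == "drop" & !is_palindromic(tab$ea, tab$oa))))
  }
  keep <- act != "drop"
  if (!any(keep)) stop("no SNPs remain after harmonization")
  dose <- dose[, keep, drop = FALSE]
  flip <- act[keep] == "flip"
  dose[, flip] <- 2 - dose[, flip]
  # mean-impute missing dosages from the (harmonized) sample frequency
  if (anyNA(dose)) {
    mu <- colMeans(dose, na.rm = TRUE)
    for (j in which(colSums(is.na(dose)) > 0)) {
      dose[is.na(dose[, j]), j] <- mu[j]
    }
  }
  score <- drop(dose %*% tab$weight[keep])
  attr(score, "n_snps_used") <- sum(keep)
  score
}

#' Calibrate a raw allele score to exposure standard deviations
#'
#' Estimates the calibration constant -- exposure s.d. per raw score unit --
#' as the ordinary least squares slope of the (standardised) exposure on the
#' raw score. Dividing the raw score by this constant yields a score in which
#' one unit corresponds to one s.d. of the exposure; regressing the outcome
#' on the calibrated score is then the ratio (two-stage) estimator.
#'
#' @param score Raw per-individual score from [build_score()].
#' @param exposure Exposure measurements on the s.d. scale.
#' @return The calibration constant (slope), with attribute `se`.
#' @export
calibrate_score <- function(score, exposure) {
  if (stats::sd(score) == 0) stop("score has no variance")
  fit <- stats::lm(exposure ~ score)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("score-exposure coefficient must be positive for calibration")
  }
  attr(slope, "se") <- summary(fit)$coefficients[2L, 2L]
  slope
}
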