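#' Causal estimate container
#'
#' @param trait Exposure trait label.
#' @param beta Log odds ratio of outcome per +1 s.d. exposure.
#' @param se Standard error of `beta`.
#' @param n_snps Number of instrument SNPs used.
#' @param flag `"ok"` or a diagnostic flag (e.g. `"separation"`).
#' @return A `causal_estimate` object with ratio-scale `or_per_sd`,
#'   `ci_low`, `ci_high` and two-sided `p` derived from `beta` and `se`.
#' @export
causal_estimate <- function(trait, beta, se, n_snps = NA_integer_,
                            flag = "ok") {
  z <- stats::qnorm(0.975)
  structure(list(
    trait = trait, beta = beta, se = se,
    or_per_sd = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p = min(1, 2 * stats::pnorm(-abs(beta / se))),
    n_snps = n_snps, flag = flag
  ), class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("Causal estimate for '%s' (%s instrument SNP%s)\n",
              x$trait, x$n_snps, if (isTRUE(x$n_snps == 1L)) "" else "s"))
  cat(sprintf("  OR per +1 s.d.: %s, p = %.3g\n",
              fmt_or_ci(x$or_per_sd, x$ci_low, x$ci_high), x$p))
  if (!identical(x$flag, "ok")) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' Individual-level Mendelian randomization via a calibrated allele score
#'
#' Logistic regression of the binary outcome on the calibrated allele score
#' (raw score divided by the calibration constant) plus optional covariates.
#' The coefficient is the log odds ratio of outcome per +1 s.d. of the
#' exposure instrumented by the score. The reported standard error is the
#' first-order (delta method) one that conditions on the calibration
#' constant, ignoring its sampling variability.
#'
#' @param score Raw per-individual score, e.g. from [build_score()].
#' @param outcome Binary 0/1 outcome; both classes required.
#' @param covariates Optional covariate matrix.
#' @param calibration Exposure s.d. per raw score unit, e.g. from
#'   [calibrate_score()]; default 1 (weights already in s.d. units).
#' @param trait Trait label for the result.
#' @return A [causal_estimate()]; quasi-separated fits are flagged.
#' @export
mr_individual <- function(score, outcome, covariates = NULL, calibration = 1,
                          trait = "exposure") {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L) stop("both outcome classes must be present")
  if (stats::sd(score) == 0) stop("score has no variance")
  s <- score / calibration
  X <- cbind(`(Intercept)` = 1, score = s,
             if (is.null(covariates)) NULL else as.matrix(covariates))
  fit <- suppressWarnings(stats::glm.fit(X, outcome, family = stats::binomial()))
  b <- fit$coefficients[["score"]]
  flag <- if (!fit$converged || abs(b) > 15) "separation" else "ok"
  V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  causal_estimate(trait, beta = b, se = sqrt(V[2L, 2L]),
                  n_snps = attr(score, "n_snps_used") %||% NA_integer_,
                  flag = flag)
}

# Align outcome summary statistics to a score definition's effect alleles.
# Swapped orientation flips the sign of beta (and complements eaf).
harmonize_stats_to_score <- function(stats_tab, weights) {
  tab <- weights$snps
  idx <- match(tab$snp, stats_tab$snp)
  if (anyNA(idx)) {
    stop(sprintf("score SNP(s) missing from summary statistics: %s",
                 paste(tab$snp[is.na(idx)], collapse = ", ")))
  }
  st <- stats_tab[idx, , drop = FALSE]
  act <- resolve_orientation(tab$ea, tab$oa, st$ea, st$oa,
                             w_eaf = tab$eaf %||% NULL,
                             g_eaf = st$eaf %||% NULL)
  keep <- act != "drop"
  if (!all(keep)) {
    warning(sprintf("%d SNP(s) dropped during harmonization", sum(!keep)))
  }
  st <- st[keep, , drop = FALSE]
  flip <- act[keep] == "flip"
  st$beta[flip] <- -st$beta[flip]
  if (!is.null(st$eaf)) st$eaf[flip] <- 1 - st$eaf[flip]
  list(stats = st, weights = tab$weight[keep], snp = tab$snp[keep])
}

#' Summary-statistic Mendelian randomization for a weighted allele score
#'
#' Approximates the association of the weighted allele score with the outcome
#' from per-SNP outcome summary statistics alone: with weights `w_j` (exposure
#' s.d. per allele) and outcome log odds ratios `b_j` with standard errors
#' `s_j`, the combined effect per +1 s.d. exposure is
#' `sum(w_j b_j / s_j^2) / sum(w_j^2 / s_j^2)` with standard error
#' `1 / sqrt(sum(w_j^2 / s_j^2))`. This is algebraically the inverse-variance
#' weighted average of the per-SNP Wald ratios `b_j / w_j` with weights
#' `w_j^2 / s_j^2`.
#'
#' @param snp_outcome_effects A `variant_stats` data frame (columns `snp`,
#'   `ea`, `oa`, `beta`, `se`, optionally `eaf`) of SNP-outcome associations.
#' @param weights A [score_definition()]; alleles are harmonized to it before
#'   combining.
#' @return A [causal_estimate()].
#' @export
mr_summary <- function(snp_outcome_effects, weights) {
  stopifnot(inherits(weights, "score_definition"))
  h <- harmonize_stats_to_score(snp_outcome_effects, weights)
  if (nrow(h$stats) == 0L) stop("no SNPs left after harmonization")
  w <- h$weights; b <- h$stats$beta; s <- h$stats$se
  if (any(s <= 0)) stop("all standard errors must be positive")
  denom <- sum(w^2 / s^2)
  causal_estimate(weights$trait,
                  beta = sum(w * b / s^2) / denom,
                  se = 1 / sqrt(denom),
                  n_snps = nrow(h$stats))
}

#' Per-SNP sensitivity analysis and funnel-plot table
#'
#' Computes, for each instrument SNP, the Wald ratio (outcome log-OR per s.d.
#' exposure through that SNP alone, `beta_j / w_j`) with first-order standard
#' error `se_j / |w_j|`, pairs each with its precision `1/se` for funnel
#' plotting, and flags SNPs whose ratio differs from the combined
#' [mr_summary()] estimate by more than 3 of their own standard errors --
#' candidate pleiotropic outliers.
#'
#' @inheritParams mr_summary
#' @return A `snp_sensitivity` data frame (`snp`, `wald_ratio`, `se`,
#'   `precision`, `flagged`) with the combined estimate as attribute
#'   `combined`.
#' @export
per_snp_sensitivity <- function(snp_outcome_effects, weights) {
  stopifnot(inherits(weights, "score_definition"))
  h <- harmonize_stats_to_score(snp_outcome_effects, weights)
  if (nrow(h$stats) < 2L) stop("at least two SNPs are required")
  if (any(h$weights == 0)) stop("zero weights give undefined Wald ratios")
  combined <- mr_summary(snp_outcome_effects, weights)
  ratio <- h$stats$beta / h$weights
  se <- h$stats$se / abs(h$weights)
  out <- data.frame(snp = h$snp, wald_ratio = ratio, se = se,
                    precision = 1 / se,
                    flagged = abs(ratio - combined$beta) > 3 * se,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_sensitivity", "data.frame")
  attr(out, "combined") <- combined
  out
}

#' Bonferroni screen across tested exposure traits
#'
#' Labels each causal estimate significant when its p-value is below
#' `0.05 / n_traits` (e.g. 0.05/15 = 0.0033 when fifteen traits are tested).
#'
#' @param p_values Two-sided p-values, one per tested trait.
#' @param n_traits Number of traits tested (>= 1); defaults to
#'   `length(p_values)`.
#' @return A list with `threshold` and logical `significant`.
#' @export
trait_screen <- function(p_values, n_traits = length(p_values)) {
  if (n_traits < 1) stop("`n_traits` must be >= 1")
  threshold <- 0.05 / n_traits
  list(threshold = threshold, significant = p_values < threshold)
}

#' Cumulative risk-score association with a log-transformed quantitative trait
#'
#' Regresses the natural log of a strictly positive quantitative trait (e.g.
#' serum AMH concentration) on the weighted risk-allele score by ordinary
#' least squares, the additive linear framework for testing whether disease
#' risk alleles shift a biomarker in aggregate.
#'
#' @param weights A [score_definition()] of risk SNPs.
#' @param genotypes Dosage matrix (see [build_score()]).
#' @param quant_trait Strictly positive trait values.
#' @param geno_alleles Optional allele map passed to [build_score()].
#' @return A list with `slope`, `se`, `p` (per raw score unit) and `n`.
#' @export
cumulative_score_trait <- function(weights, genotypes, quant_trait,
                                   geno_alleles = NULL) {
  if (any(quant_trait <= 0)) {
    stop("trait must be strictly positive before log transformation")
  }
  score <- build_score(weights, genotypes, geno_alleles)
  fit <- stats::lm(log(quant_trait) ~ score)
  cf <- summary(fit)$coefficients
  list(slope = cf[2L, 1L], se = cf[2L, 2L], p = cf[2L, 4L],
       n = length(quant_trait))
}
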