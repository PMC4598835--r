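#' Per-SNP additive-model logistic association
#'
#' Fits, for every SNP column, a maximum-likelihood logistic regression of the
#' binary outcome on the allele dosage (0/1/2 copies of the effect allele)
#' plus optional covariates, by iteratively reweighted least squares. Effects
#' are reported as Wald log odds ratios with standard errors and two-sided
#' normal-approximation p-values. Fits that fail to converge within the
#' iteration cap, or that diverge under quasi-complete separation
#' (|beta| > 15), are flagged rather than reported as estimates.
#'
#' @param genotypes Numeric matrix, individuals x SNPs; dosages of the effect
#'   allele. Column names become variant ids.
#' @param outcome Binary 0/1 vector; both classes must be present.
#' @param covariates Optional numeric matrix of covariates (no intercept
#'   column; one is added internally).
#' @param chrom,pos Optional per-SNP coordinates carried into the output.
#' @param effect_allele,other_allele Optional per-SNP allele labels.
#' @param max_iter IRLS iteration cap.
#'
#' @return A `variant_stats` data frame with columns `snp`, `chr`, `pos`,
#'   `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n_cases`, `n_controls`, `flag`
#'   (`"ok"`, `"separation"` or `"no_convergence"`; flagged rows carry `NA`
#'   estimates).
#' @export
logistic_assoc <- function(genotypes, outcome, covariates = NULL,
                           chrom = NULL, pos = NULL,
                           effect_allele = NULL, other_allele = NULL,
                           max_iter = 25L) {
  genotypes <- as.matrix(genotypes)
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop("`outcome` must be binary 0/1")
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present")
  }
  if (nrow(genotypes) != length(outcome)) {
    stop("`genotypes` and `outcome` have incompatible sizes")
  }
  m <- ncol(genotypes)
  ids <- colnames(genotypes) %||% paste0("snp", seq_len(m))
  cov_mat <- if (is.null(covariates)) NULL else as.matrix(covariates)

  beta <- se <- p <- rep(NA_real_, m)
  flag <- rep("ok", m)
  for (j in seq_len(m)) {
    X <- cbind(`(Intercept)` = 1, dose = genotypes[, j], cov_mat)
    fit <- suppressWarnings(
      stats::glm.fit(X, outcome, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = max_iter)))
    b <- fit$coefficients[["dose"]]
    if (!fit$converged) {
      flag[j] <- "no_convergence"
    } else if (!is.finite(b) || abs(b) > 15) {
      flag[j] <- "separation"
    } else {
      XtWX <- crossprod(X * sqrt(fit$weights))
      V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      if (is.null(V)) {
        flag[j] <- "separation"
      } else {
        beta[j] <- b
        se[j] <- sqrt(V[2L, 2L])
        p[j] <- min(1, 2 * stats::pnorm(-abs(b / se[j])))
      }
    }
  }

  out <- data.frame(
    snp = ids,
    chr = if (is.null(chrom)) NA_character_ else as.character(chrom),
    pos = if (is.null(pos)) NA_integer_ else as.integer(pos),
    ea = effect_allele %||% NA_character_,
    oa = other_allele %||% NA_character_,
    eaf = colMeans(genotypes) / 2,
    beta = beta, se = se, p = p,
    n_cases = sum(outcome), n_controls = sum(outcome == 0L),
    flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_stats", "data.frame")
  out
}

#' Genomic control of association test statistics
#'
#' Computes the inflation factor lambda as the ratio of the observed median
#' 1-d.f. chi-square statistic to its theoretical null median (about 0.4549).
#' When lambda exceeds 1 every statistic is divided by it and p-values are
#' recomputed from the chi-square(1) distribution; deflation (lambda <= 1) is
#' left uncorrected, the standard convention.
#'
#' @param chisq_stats Non-negative 1-d.f. chi-square statistics (e.g.
#'   `(beta/se)^2`).
#' @return A list of class `gc_result` with `lambda`, `chisq_adj`, `p_adj`.
#' @examples
#' gc <- genomic_control(rchisq(1e4, 1) * 1.05)
#' gc$lambda
#' @export
genomic_control <- function(chisq_stats) {
  if (length(chisq_stats) == 0L) stop("no statistics supplied")
  if (any(!is.finite(chisq_stats)) || any(chisq_stats < 0)) {
    stop("statistics must be finite and non-negative")
  }
  lambda <- stats::median(chisq_stats) / stats::qchisq(0.5, df = 1)
  adj <- if (lambda > 1) chisq_stats / lambda else chisq_stats
  structure(list(lambda = lambda,
                 chisq_adj = adj,
                 p_adj = stats::pchisq(adj, df = 1, lower.tail = FALSE)),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Genomic control: lambda = %.4f (%s)\n", x$lambda,
              if (x$lambda > 1) "statistics deflated" else "no adjustment"))
  invisible(x)
}
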