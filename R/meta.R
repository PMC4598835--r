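#' One study's effect estimate on the log-odds scale
#'
#' @param beta Log-scale effect.
#' @param se Standard error of `beta` (> 0, or 0 only in the degenerate
#'   point-CI case produced by [ci_to_se()]).
#' @param label Study name.
#' @return A one-row `study_effect` data frame.
#' @export
study_effect <- function(beta, se, label = NA_character_) {
  if (!is.finite(beta) || !is.finite(se) || se < 0) {
    stop("`beta` must be finite and `se` non-negative")
  }
  structure(data.frame(label = label, beta = beta, se = se,
                       stringsAsFactors = FALSE),
            class = c("study_effect", "data.frame"))
}

#' Convert a printed odds ratio with confidence interval to log scale
#'
#' Recovers `beta = ln(OR)` and `se = ln(ci_high / ci_low) / (2 z)` with
#' `z = qnorm(1 - (1 - level) / 2)` (1.959964 at the default 95% level), the
#' standard back-calculation for symmetric Wald intervals on the log scale.
#' A degenerate point interval (`ci_low == ci_high`) yields `se = 0` with a
#' warning, since no sampling variability can be recovered from it.
#'
#' @param or_point Ratio-scale point estimate.
#' @param ci_low,ci_high Ratio-scale confidence bounds,
#'   `0 < ci_low <= or_point <= ci_high`.
#' @param level Confidence level of the interval.
#' @param label Study name carried along.
#' @return A [study_effect()].
#' @examples
#' ci_to_se(1.60, 1.35, 1.91)   # beta ~ 0.470, se ~ 0.0885
#' @export
ci_to_se <- function(or_point, ci_low, ci_high, level = 0.95,
                     label = NA_character_) {
  if (any(c(or_point, ci_low, ci_high) <= 0)) {
    stop("ratio-scale inputs must be positive")
  }
  if (ci_low > or_point || or_point > ci_high) {
    stop("require ci_low <= or_point <= ci_high")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- log(ci_high / ci_low) / (2 * z)
  if (se == 0) warning("degenerate interval: se = 0")
  study_effect(beta = log(or_point), se = se, label = label)
}

#' Fixed-effect inverse-variance meta-analysis with Cochran's Q
#'
#' Combines log-scale study effects with weights `1/se^2`: pooled
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`, two-sided normal p.
#' Heterogeneity is measured by Cochran's `Q = sum(w (b - pooled)^2)`,
#' referred to chi-square with `k - 1` degrees of freedom.
#'
#' @param effects A data frame with columns `beta` and `se` (one row per
#'   study; [study_effect()] rows can be `rbind`-ed), or a list of
#'   `study_effect`s.
#' @return A list of class `meta_result` with `beta`, `se`, `p`, `or`,
#'   `ci_low`, `ci_high` (95%, ratio scale), `q_stat`, `q_df`, `p_het`,
#'   `n_studies`.
#' @examples
#' eff <- rbind(ci_to_se(1.60, 1.35, 1.91, label = "discovery"),
#'              ci_to_se(1.57, 1.02, 2.43, label = "follow-up"))
#' ivw_meta(eff)
#' @export
ivw_meta <- function(effects) {
  if (is.list(effects) && !is.data.frame(effects)) {
    effects <- do.call(rbind, effects)
  }
  if (!is.data.frame(effects) || !all(c("beta", "se") %in% names(effects)) ||
      nrow(effects) == 0L) {
    stop("`effects` must hold at least one study with `beta` and `se`")
  }
  if (any(effects$se <= 0)) stop("all standard errors must be positive")
  w <- 1 / effects$se^2
  beta <- sum(w * effects$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  k <- nrow(effects)
  q <- sum(w * (effects$beta - beta)^2)
  z <- stats::qnorm(0.975)
  structure(list(
    beta = beta, se = se,
    p = min(1, 2 * stats::pnorm(-abs(beta / se))),
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    q_stat = q, q_df = k - 1L,
    p_het = if (k > 1L) stats::pchisq(q, df = k - 1L, lower.tail = FALSE)
            else NA_real_,
    n_studies = k
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d studies\n", x$n_studies))
  cat(sprintf("  OR %s, p = %.3g\n",
              fmt_or_ci(x$or, x$ci_low, x$ci_high), x$p))
  if (!is.na(x$p_het)) {
    cat(sprintf("  Cochran's Q = %.3f on %d d.f., P_het = %.3g\n",
                x$q_stat, x$q_df, x$p_het))
  }
  invisible(x)
}
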