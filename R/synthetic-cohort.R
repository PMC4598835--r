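#' Configuration for a synthetic case-control cohort
#'
#' Bundles and validates the parameters of the instrumental-variable data
#' generating process used throughout the package: unlinked SNPs in
#' Hardy-Weinberg equilibrium, a quantitative exposure built additively from
#' the SNPs plus Gaussian noise, and a binary outcome from a logistic model
#' with a stated causal log odds ratio per standard deviation of exposure.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param allele_freqs Effect-allele frequencies, all strictly in (0, 1).
#' @param snp_effects_on_exposure Per-allele effects on the exposure, in
#'   exposure standard-deviation units; same length as `allele_freqs`.
#' @param causal_log_or Log odds ratio of the outcome per +1 s.d. exposure.
#' @param baseline_prevalence Target marginal outcome prevalence, in (0, 1).
#' @param exposure_noise_sd Standard deviation of the non-genetic exposure
#'   component.
#' @param seed Integer seed; every draw in [simulate_cohort()] comes from one
#'   generator seeded with it, leaving the global RNG untouched.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_individuals, allele_freqs, snp_effects_on_exposure,
                       causal_log_or = 0, baseline_prevalence = 0.06,
                       exposure_noise_sd = 1, seed = 1L) {
  if (length(allele_freqs) == 0L) stop("at least one SNP is required")
  stop_if_not_prob(allele_freqs, "allele_freqs")
  stop_if_not_prob(baseline_prevalence, "baseline_prevalence")
  if (length(snp_effects_on_exposure) != length(allele_freqs)) {
    stop("`allele_freqs` and `snp_effects_on_exposure` must have equal length")
  }
  if (!all(is.finite(snp_effects_on_exposure))) {
    stop("`snp_effects_on_exposure` must be finite")
  }
  if (!is.finite(causal_log_or)) stop("`causal_log_or` must be finite")
  if (exposure_noise_sd < 0) stop("`exposure_noise_sd` must be >= 0")
  structure(list(
    n_individuals = as.integer(n_individuals),
    allele_freqs = as.numeric(allele_freqs),
    snp_effects_on_exposure = as.numeric(snp_effects_on_exposure),
    causal_log_or = causal_log_or,
    baseline_prevalence = baseline_prevalence,
    exposure_noise_sd = exposure_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a genotyped cohort with exposure and binary outcome
#'
#' Genotypes are drawn per SNP as Binomial(2, freq) (Hardy-Weinberg
#' equilibrium, no linkage). The exposure is the additive genetic score plus
#' Normal(0, `exposure_noise_sd`) noise, standardised within-sample to unit
#' variance so that "per 1 s.d." refers to the realised exposure scale. The
#' outcome is Bernoulli with logit `alpha + causal_log_or * exposure`, with
#' the intercept `alpha` solved by bisection so that the model-implied
#' marginal prevalence matches `baseline_prevalence` to 1e-3.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_cohort` with elements `genotypes` (an
#'   `n x m` integer dosage matrix, columns named `snp1..snpm`), `exposure`
#'   (standardised numeric vector), `outcome` (0/1 integer vector), and
#'   `config`.
#' @examples
#' cfg <- sim_config(500, allele_freqs = c(0.3, 0.5),
#'                   snp_effects_on_exposure = c(0.2, 0.1),
#'                   causal_log_or = log(1.9), seed = 7)
#' coh <- simulate_cohort(cfg)
#' mean(coh$outcome)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- length(config$allele_freqs)
  with_local_seed(config$seed, {
    g <- matrix(stats::rbinom(n * m, 2L, rep(config$allele_freqs, each = n)),
                nrow = n, ncol = m,
                dimnames = list(NULL, paste0("snp", seq_len(m))))
    x <- drop(g %*% config$snp_effects_on_exposure) +
      stats::rnorm(n, 0, config$exposure_noise_sd)
    sx <- stats::sd(x)
    if (sx > 0) x <- (x - mean(x)) / sx
    alpha <- solve_prevalence_intercept(x, config$causal_log_or,
                                        config$baseline_prevalence)
    y <- stats::rbinom(n, 1L, stats::plogis(alpha + config$causal_log_or * x))
    structure(list(genotypes = g, exposure = x, outcome = y, config = config),
              class = "sim_cohort")
  })
}

# bisection for the intercept hitting the target marginal prevalence,
# absolute tolerance 1e-3 on the prevalence scale
solve_prevalence_intercept <- function(x, beta, prevalence, tol = 1e-3) {
  f <- function(a) mean(stats::plogis(a + beta * x)) - prevalence
  lo <- -30; hi <- 30
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol || (hi - lo) < 1e-10) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs, %d cases (%.1f%%)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$outcome),
              100 * mean(x$outcome)))
  invisible(x)
}

#' Simulate a multi-population allele-frequency panel under drift
#'
#' Each population's frequency at each SNP is drawn independently from a Beta
#' distribution with mean equal to the ancestral frequency `p` and variance
#' `drift_fst * p * (1 - p)` -- the Balding-Nichols model of divergence from
#' a shared ancestral population at a common F_ST.
#'
#' @param ancestral_freqs Ancestral derived/effect-allele frequencies,
#'   strictly in (0, 1).
#' @param n_pops Number of populations.
#' @param drift_fst Drift parameter (F_ST), strictly in (0, 1).
#' @param seed Integer seed.
#' @param sample_sizes Optional per-population haplotype counts recorded in
#'   the panel (metadata only; defaults to 100 each).
#'
#' @return A `pop_freq_panel`: list with `freqs` (population x SNP matrix),
#'   `snp_ids`, and `sample_sizes`.
#' @export
simulate_pop_freqs <- function(ancestral_freqs, n_pops, drift_fst, seed = 1L,
                               sample_sizes = NULL) {
  stop_if_not_prob(ancestral_freqs, "ancestral_freqs")
  if (!is.finite(drift_fst) || drift_fst <= 0 || drift_fst >= 1) {
    stop("`drift_fst` must be strictly inside (0, 1)")
  }
  m <- length(ancestral_freqs)
  # Beta(a, b) with a + b = 1/fst - 1 gives mean p, variance fst * p * (1 - p)
  nu <- 1 / drift_fst - 1
  with_local_seed(seed, {
    f <- matrix(stats::rbeta(n_pops * m,
                             shape1 = rep(ancestral_freqs * nu, each = n_pops),
                             shape2 = rep((1 - ancestral_freqs) * nu, each = n_pops)),
                nrow = n_pops, ncol = m,
                dimnames = list(paste0("pop", seq_len(n_pops)),
                                paste0("snp", seq_len(m))))
    f <- pmin(pmax(f, 0), 1)
    pop_freq_panel(f, sample_sizes = sample_sizes %||% rep(100L, n_pops))
  })
}

#' Construct an allele-frequency panel
#'
#' @param freqs Population x SNP matrix of allele frequencies in \[0, 1\].
#' @param snp_ids SNP identifiers (defaults to column names).
#' @param sample_sizes Haplotype counts per population.
#' @return A `pop_freq_panel` object.
#' @export
pop_freq_panel <- function(freqs, snp_ids = colnames(freqs),
                           sample_sizes = rep(100L, nrow(freqs))) {
  freqs <- as.matrix(freqs)
  stop_if_not_prob(freqs, "freqs", open = FALSE)
  if (length(sample_sizes) != nrow(freqs)) {
    stop("one sample size per population is required")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(freqs)))
  colnames(freqs) <- snp_ids
  structure(list(freqs = freqs, snp_ids = snp_ids,
                 sample_sizes = sample_sizes),
            class = "pop_freq_panel")
}

#' @export
print.pop_freq_panel <- function(x, ...) {
  cat(sprintf("Allele-frequency panel: %d populations x %d SNPs\n",
              nrow(x$freqs), ncol(x$freqs)))
  invisible(x)
}
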