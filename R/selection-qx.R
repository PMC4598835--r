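#' Qx test for polygenic selection with a frequency-matched bootstrap null
#'
#' Forms, for each population *m*, the genetic value
#' `Z_m = sum_j 2 w_j p_mj` over the tested trait-associated SNPs, and
#' measures the excess dispersion of the (mean-centred) genetic values over
#' their neutral drift expectation. Drift covariance among populations is
#' estimated from the genome-wide panel SNPs in its simplest mean-centred
#' form: each panel SNP contributes the outer product of its standardised
#' frequency deviations `(p_m - pbar) / sqrt(pbar (1 - pbar))`, and the
#' tested SNPs' additive variance `4 sum_j w_j^2 pbar_j (1 - pbar_j)` scales
#' the quadratic form, which is referred to a null distribution built by
#' resampling: every tested SNP is replaced by a random panel SNP from the
#' same minor-allele-frequency bin (`n_bins` equal-width bins on \[0, 0.5\],
#' edge ties to the lower bin), the statistic recomputed `n_boot` times, and
#' `p = (1 + #\{null >= observed\}) / (n_boot + 1)`.
#'
#' Panel SNPs whose mean minor-allele frequency falls below `panel_maf_min`
#' are excluded from the covariance estimate: the
#' `1/sqrt(pbar (1 - pbar))` standardisation is numerically unstable for
#' effectively monomorphic SNPs and lets a handful of near-fixed panel
#' variants corrupt the drift covariance (genotyping-chip reference panels
#' are ascertained towards common variants for the same reason). The
#' matching pool, by contrast, keeps every polymorphic panel SNP so that
#' tested SNPs in rare-frequency bins are matched to SNPs of like frequency.
#' An empty matching bin is widened to its nearest non-empty neighbours with
#' a warning.
#'
#' @param snp_effects Named vector of per-allele effect weights; names must
#'   be SNP ids present in `panel`.
#' @param panel A [pop_freq_panel()] whose columns include both the tested
#'   SNPs and the genome-wide SNPs used for the covariance and the bootstrap
#'   pool (tested SNPs are excluded from the pool automatically).
#' @param populations Optional subset (names or indices) of panel rows to
#'   test.
#' @param n_boot Bootstrap replicates.
#' @param n_bins Number of equal-width minor-allele-frequency matching bins.
#' @param panel_maf_min Minimum mean minor-allele frequency for a panel SNP
#'   to enter the drift-covariance estimate.
#' @param seed Integer seed for the resampling.
#' @return A list of class `qx_result` with `qx_stat`, `p_boot`, `n_boot`,
#'   `bins` (bin edges), `genetic_values` and `n_snps`.
#' @export
qx_test <- function(snp_effects, panel, populations = NULL,
                    n_boot = 10000L, n_bins = 20L, panel_maf_min = 0.05,
                    seed = 1L) {
  stopifnot(inherits(panel, "pop_freq_panel"))
  freqs <- panel$freqs
  if (!is.null(populations)) freqs <- freqs[populations, , drop = FALSE]
  if (nrow(freqs) < 2L) stop("at least two populations are required")
  ids <- names(snp_effects)
  if (is.null(ids)) stop("`snp_effects` must be named by SNP id")
  test_idx <- match(ids, colnames(freqs))
  if (anyNA(test_idx)) {
    stop(sprintf("tested SNP(s) absent from panel: %s",
                 paste(ids[is.na(test_idx)], collapse = ", ")))
  }
  w <- as.numeric(snp_effects)
  pool_idx <- setdiff(seq_len(ncol(freqs)), test_idx)
  if (length(pool_idx) < length(test_idx)) {
    stop("panel too small to serve as a bootstrap pool")
  }

  # drift covariance (rank M-1) in mean-centred form, from common panel
  # SNPs only (near-fixed SNPs have an unstable standardisation)
  pbar_pool <- colMeans(freqs[, pool_idx, drop = FALSE])
  cov_idx <- pool_idx[pmin(pbar_pool, 1 - pbar_pool) >= panel_maf_min]
  if (length(cov_idx) < 2L * nrow(freqs)) {
    stop("too few common panel SNPs to estimate the drift covariance")
  }
  pb <- colMeans(freqs[, cov_idx, drop = FALSE])
  Y <- sweep(freqs[, cov_idx, drop = FALSE], 2L, pb) /
    rep(sqrt(pb * (1 - pb)), each = nrow(freqs))
  Fmat <- tcrossprod(Y) / length(cov_idx)
  Finv <- MASS::ginv(Fmat)
  # the frequency-matching pool keeps every polymorphic panel SNP
  usable <- pool_idx[pbar_pool > 0 & pbar_pool < 1]

  qx_stat_of <- function(idx) {
    P <- freqs[, idx, drop = FALSE]
    pbar <- colMeans(P)
    va <- 4 * sum(w^2 * pbar * (1 - pbar))
    if (va == 0) return(0)
    Z <- drop(P %*% (2 * w))
    Zc <- (Z - mean(Z)) / sqrt(va)
    drop(t(Zc) %*% Finv %*% Zc)
  }
  observed <- qx_stat_of(test_idx)

  # frequency-matched resampling pool, binned on minor-allele frequency
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  maf <- function(p) pmin(p, 1 - p)
  bin_of <- function(p) {
    b <- findInterval(maf(p), edges, rightmost.closed = TRUE,
                      left.open = TRUE)   # ties at edges to the lower bin
    pmin(pmax(b, 1L), n_bins)
  }
  pool_bin <- bin_of(colMeans(freqs[, usable, drop = FALSE]))
  test_bin <- bin_of(colMeans(freqs[, test_idx, drop = FALSE]))
  pool_by_bin <- split(usable, factor(pool_bin, levels = seq_len(n_bins)))
  draw_pool <- lapply(test_bin, function(b) {
    cand <- pool_by_bin[[b]]
    widen <- 1L
    while (length(cand) == 0L) {  # widen to adjacent bins until non-empty
      nb <- c(b - widen, b + widen)
      nb <- nb[nb >= 1L & nb <= n_bins]
      cand <- unlist(pool_by_bin[nb], use.names = FALSE)
      widen <- widen + 1L
    }
    cand
  })
  if (any(lengths(pool_by_bin)[test_bin] == 0L)) {
    warning("empty frequency bin widened to adjacent bin(s)")
  }

  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- vapply(draw_pool, function(cand)
        if (length(cand) == 1L) cand else sample(cand, 1L), integer(1))
      qx_stat_of(idx)
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (n_boot + 1)

  structure(list(qx_stat = observed, p_boot = p, n_boot = n_boot,
                 bins = edges, genetic_values = drop(
                   freqs[, test_idx, drop = FALSE] %*% (2 * w)),
                 n_snps = length(test_idx)),
            class = "qx_result")
}

#' @export
print.qx_result <- function(x, ...) {
  cat(sprintf("Qx polygenic selection test: Qx = %.3f over %d SNPs, P = %.4g (%d bootstraps)\n",
              x$qx_stat, x$n_snps, x$p_boot, x$n_boot))
  invisible(x)
}
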