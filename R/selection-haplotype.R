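# Extended haplotype homozygosity and derived statistics (iHS, DIND).
# Haplotype identity is tracked by partition refinement outward from the
# focal site; homozygosity at a marker is sum n_c (n_c - 1) / (n (n - 1))
# over the distinct extended haplotypes c.

# EHH values at each marker moving away from `focal` in `direction` (+1/-1)
# for the haplotype rows `rows`. Returns positions and EHH including the
# focal site itself (EHH = 1).
ehh_one_side <- function(hap, positions, focal, rows, direction,
                         stop_below = 0) {
  n <- length(rows)
  cols <- if (direction > 0) seq(focal, ncol(hap)) else seq(focal, 1L)
  ehh <- numeric(length(cols))
  ehh[1L] <- 1
  ids <- rep(1L, n)
  last <- length(cols)
  for (k in seq_along(cols)[-1L]) {
    ids <- ids * 2L + hap[rows, cols[k]]
    ids <- match(ids, unique(ids))          # re-densify to avoid overflow
    cnt <- tabulate(ids)
    ehh[k] <- sum(cnt * (cnt - 1)) / (n * (n - 1))
    if (ehh[k] < stop_below) { last <- k; break }  # EHH cannot recover
  }
  list(pos = positions[cols[1:last]], ehh = ehh[1:last])
}

#' Extended haplotype homozygosity around a focal allele
#'
#' EHH at a marker is the probability that two random haplotypes carrying
#' `allele` at the focal site are identical at every site between the focal
#' site and that marker (inclusive); it equals 1 at the focal site and decays
#' monotonically outward.
#'
#' @param hap A [haplotype_matrix()].
#' @param allele Focal allele class, 1 = derived (default) or 0 = ancestral.
#' @param focal Focal site column index (defaults to `hap$focal_site`).
#' @return A list with `left` and `right`, each holding `pos` and `ehh`
#'   ordered outward from the focal site.
#' @export
ehh <- function(hap, allele = 1L, focal = hap$focal_site) {
  stopifnot(inherits(hap, "haplotype_matrix"), !is.na(focal))
  rows <- which(hap$haplotypes[, focal] == allele)
  if (length(rows) < 2L) stop("fewer than two haplotypes carry the allele")
  list(left = ehh_one_side(hap$haplotypes, hap$positions, focal, rows, -1L),
       right = ehh_one_side(hap$haplotypes, hap$positions, focal, rows, +1L))
}

# trapezoidal integral of an EHH curve outward from the focal site,
# truncated at the last marker with EHH >= threshold
integrate_ehh <- function(pos, ehh, threshold) {
  stop_at <- which(ehh < threshold)
  last <- if (length(stop_at)) stop_at[1L] - 1L else length(ehh)
  if (last < 2L) return(0)
  sum(abs(diff(pos[1:last])) * (ehh[1:(last - 1L)] + ehh[2:last]) / 2)
}

#' Unstandardised integrated haplotype score at the focal site
#'
#' Computes EHH outward from the focal site separately for haplotypes
#' carrying the derived and the ancestral allele, integrates each curve over
#' physical position by the trapezoidal rule until EHH drops below
#' `min_ehh` (or the data edge), sums left and right integrals into iHH, and
#' returns `ln(iHH_ancestral / iHH_derived)`. Long derived-allele haplotypes
#' (a sweep signature) drive the score negative. Standardisation within
#' derived-frequency bins is a separate step ([standardize_ihs()]).
#'
#' @param hap A [haplotype_matrix()] with a polymorphic focal site. Callers
#'   following the usual scan convention should pre-filter to focal minor
#'   allele frequency > 0.2.
#' @param min_ehh EHH truncation threshold for the integral.
#' @param focal Focal site column (defaults to `hap$focal_site`).
#' @return A list of class `ihs_result`: `ihs` (unstandardised, `NA` when
#'   undefined), `ihh_ancestral`, `ihh_derived`, `freq_derived`, `flag`.
#' @export
ihs <- function(hap, min_ehh = 0.05, focal = hap$focal_site) {
  stopifnot(inherits(hap, "haplotype_matrix"), !is.na(focal))
  f <- mean(hap$haplotypes[, focal])
  if (f == 0 || f == 1) stop("focal site must be polymorphic")
  ihh <- vapply(c(ancestral = 0L, derived = 1L), function(a) {
    rows <- which(hap$haplotypes[, focal] == a)
    if (length(rows) < 2L) return(NA_real_)
    e <- list(left = ehh_one_side(hap$haplotypes, hap$positions, focal, rows,
                                  -1L, stop_below = min_ehh),
              right = ehh_one_side(hap$haplotypes, hap$positions, focal, rows,
                                   +1L, stop_below = min_ehh))
    integrate_ehh(e$left$pos, e$left$ehh, min_ehh) +
      integrate_ehh(e$right$pos, e$right$ehh, min_ehh)
  }, numeric(1))
  flag <- "ok"
  score <- NA_real_
  if (anyNA(ihh)) {
    flag <- "class_too_small"
  } else if (ihh[["derived"]] == 0 || ihh[["ancestral"]] == 0) {
    flag <- "zero_ihh"
  } else {
    score <- log(ihh[["ancestral"]] / ihh[["derived"]])
  }
  structure(list(ihs = score, ihh_ancestral = ihh[["ancestral"]],
                 ihh_derived = ihh[["derived"]], freq_derived = f,
                 flag = flag),
            class = "ihs_result")
}

#' Standardise iHS scores within derived-allele-frequency bins
#'
#' Raw iHS depends on the derived allele frequency; scores are therefore
#' centred and scaled within equal-width frequency bins: for each bin the
#' mean and standard deviation of the member scores are subtracted and
#' divided out. Bins with fewer than two scores yield `NA`.
#'
#' @param scores Unstandardised iHS values.
#' @param freqs Derived-allele frequencies, one per score.
#' @param n_bins Number of equal-width bins on \[0, 1\].
#' @return Standardised scores (mean ~0, s.d. ~1 within each bin).
#' @export
standardize_ihs <- function(scores, freqs, n_bins = 20L) {
  stopifnot(length(scores) == length(freqs))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(freqs, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  out <- rep(NA_real_, length(scores))
  for (b in unique(bin)) {
    i <- which(bin == b & !is.na(scores))
    if (length(i) < 2L) next
    s <- stats::sd(scores[i])
    if (s == 0) next
    out[i] <- (scores[i] - mean(scores[i])) / s
  }
  out
}

#' Derived intra-allelic nucleotide diversity (DIND) statistic
#'
#' Splits the haplotypes by their allele at the focal site and computes
#' nucleotide diversity pi -- the mean number of pairwise differences per
#' site -- within each class over the sites lying within `window` bases of
#' the focal position (the focal site itself excluded). The statistic is
#' `pi_ancestral / pi_derived`; a recent sweep leaves derived haplotypes
#' nearly identical, inflating the ratio. A derived class with zero
#' diversity yields `Inf` with a flag.
#'
#' @param hap A [haplotype_matrix()] with a polymorphic focal site and at
#'   least two haplotypes in each allele class.
#' @param window Half-width in bases of the window around the focal site.
#' @param focal Focal site column (defaults to `hap$focal_site`).
#' @return A list of class `dind_result`: `statistic`, `pi_ancestral`,
#'   `pi_derived`, `n_sites`, `flag`.
#' @export
dind <- function(hap, window = Inf, focal = hap$focal_site) {
  stopifnot(inherits(hap, "haplotype_matrix"), !is.na(focal))
  alleles <- hap$haplotypes[, focal]
  if (all(alleles == alleles[1L])) stop("focal site must be polymorphic")
  if (min(sum(alleles == 0L), sum(alleles == 1L)) < 2L) {
    stop("at least two haplotypes are required in each allele class")
  }
  in_win <- abs(hap$positions - hap$positions[focal]) <= window
  in_win[focal] <- FALSE
  cols <- which(in_win)
  pi_of <- function(rows) {
    n <- length(rows)
    if (length(cols) == 0L) return(0)
    cnt <- colSums(hap$haplotypes[rows, cols, drop = FALSE])
    sum(cnt * (n - cnt)) / choose(n, 2) / length(cols)
  }
  pi_a <- pi_of(which(alleles == 0L))
  pi_d <- pi_of(which(alleles == 1L))
  flag <- "ok"
  stat <- if (pi_d == 0) { flag <- "zero_derived_diversity"; Inf } else
    pi_a / pi_d
  structure(list(statistic = stat, pi_ancestral = pi_a, pi_derived = pi_d,
                 n_sites = length(cols), flag = flag),
            class = "dind_result")
}
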