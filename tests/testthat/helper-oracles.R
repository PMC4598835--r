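# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct route available (explicit Newton iterations, generalized
# least squares, exhaustive pair/subset enumeration) so that agreement with
# the package implementation is a genuine cross-check.

# maximum-likelihood logistic regression by explicit Newton-Raphson on the
# full log-likelihood (intercept + one dosage term)
oracle_logistic_newton <- function(dose, y, tol = 1e-12, max_iter = 50) {
  X <- cbind(1, dose)
  b <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * (mu * (1 - mu)), X)
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  V <- solve(crossprod(X * (mu * (1 - mu)), X))
  list(beta = unname(b[2]), se = sqrt(V[2, 2]))
}

# fixed-effect pooled estimate as a generalized least squares fit of the
# study effects on a unit design with covariance diag(se^2)
oracle_gls_pooled <- function(beta, se) {
  Vinv <- diag(1 / se^2, length(se))
  X <- matrix(1, length(beta), 1)
  xvx <- solve(t(X) %*% Vinv %*% X)
  b <- drop(xvx %*% t(X) %*% Vinv %*% beta)
  list(beta = b, se = sqrt(drop(xvx)))
}

# EHH by exhaustive enumeration of haplotype pairs: probability that a
# random pair carrying `allele` at `focal` is identical on all sites from
# the focal column to column k
oracle_ehh <- function(hap_mat, positions, focal, allele, direction) {
  rows <- which(hap_mat[, focal] == allele)
  n <- length(rows)
  cols <- if (direction > 0) seq(focal, ncol(hap_mat)) else seq(focal, 1L)
  pairs <- utils::combn(rows, 2)
  ehh <- vapply(seq_along(cols), function(k) {
    seg <- cols[1:k]
    same <- vapply(seq_len(ncol(pairs)), function(q) {
      all(hap_mat[pairs[1, q], seg] == hap_mat[pairs[2, q], seg])
    }, logical(1))
    sum(same) / choose(n, 2)
  }, numeric(1))
  list(pos = positions[cols], ehh = ehh)
}

oracle_integrate <- function(pos, ehh, threshold = 0.05) {
  below <- which(ehh < threshold)
  last <- if (length(below)) below[1] - 1 else length(ehh)
  if (last < 2) return(0)
  total <- 0
  for (k in 2:last) {
    total <- total + abs(pos[k] - pos[k - 1]) * (ehh[k] + ehh[k - 1]) / 2
  }
  total
}

oracle_ihs <- function(hap, threshold = 0.05) {
  f <- hap$focal_site
  ihh <- sapply(c(0, 1), function(a) {
    l <- oracle_ehh(hap$haplotypes, hap$positions, f, a, -1)
    r <- oracle_ehh(hap$haplotypes, hap$positions, f, a, +1)
    oracle_integrate(l$pos, l$ehh, threshold) +
      oracle_integrate(r$pos, r$ehh, threshold)
  })
  log(ihh[1] / ihh[2])
}

# nucleotide diversity by full pair enumeration within one allele class
oracle_pi <- function(hap_mat, rows, cols) {
  if (length(cols) == 0) return(0)
  pairs <- utils::combn(rows, 2)
  d <- vapply(seq_len(ncol(pairs)), function(q) {
    sum(hap_mat[pairs[1, q], cols] != hap_mat[pairs[2, q], cols])
  }, numeric(1))
  mean(d) / length(cols)
}

oracle_dind <- function(hap, window) {
  f <- hap$focal_site
  alleles <- hap$haplotypes[, f]
  cols <- setdiff(which(abs(hap$positions - hap$positions[f]) <= window), f)
  oracle_pi(hap$haplotypes, which(alleles == 0), cols) /
    oracle_pi(hap$haplotypes, which(alleles == 1), cols)
}

# best local SNP p per gene by a direct window scan
oracle_gene_scores <- function(stats, genes, upstream, downstream) {
  vapply(seq_len(nrow(genes)), function(i) {
    minus <- genes$strand[i] == "-"
    ws <- if (minus) genes$start[i] - downstream else genes$start[i] - upstream
    we <- if (minus) genes$end[i] + upstream else genes$end[i] + downstream
    hit <- stats$chr == genes$chrom[i] & stats$pos >= ws + 1 & stats$pos <= we
    if (any(hit)) min(stats$p[hit]) else NA_real_
  }, numeric(1))
}

# greedy lead-SNP selection by repeated global minimum
oracle_leads <- function(stats, half_window = 5e5) {
  remaining <- stats
  leads <- character(0)
  while (nrow(remaining) > 0) {
    i <- which.min(remaining$p)
    leads <- c(leads, remaining$snp[i])
    keep <- !(remaining$chr == remaining$chr[i] &
                abs(remaining$pos - remaining$pos[i]) <= half_window)
    remaining <- remaining[keep, , drop = FALSE]
  }
  sort(leads)
}

# a small cohort + matching score definition used by several MR tests
make_mr_fixture <- function(n = 20000, m = 15, causal_log_or = log(1.6),
                            seed = 42) {
  set.seed(seed)
  freqs <- runif(m, 0.15, 0.85)
  effects <- runif(m, 0.03, 0.12)
  cfg <- sim_config(n, freqs, effects, causal_log_or = causal_log_or,
                    baseline_prevalence = 0.06, seed = seed)
  coh <- simulate_cohort(cfg)
  weights <- score_definition("exposure", data.frame(
    snp = colnames(coh$genotypes), ea = "A", oa = "G", weight = effects,
    eaf = freqs, stringsAsFactors = FALSE))
  list(cohort = coh, weights = weights, config = cfg)
}
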