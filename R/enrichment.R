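#' Gene scores from best local SNP p-values
#'
#' Maps every gene to the lowest SNP p-value within a window extending
#' `upstream` bases beyond the transcript start and `downstream` bases beyond
#' the end on the + strand (the window is flipped for - strand genes). Window
#' boundaries are closed: a SNP exactly at the boundary is included. Genes
#' with no SNP in their window are left unscored; genes overlapping any
#' exclusion region (e.g. the HLA region) are dropped.
#'
#' @param summary_stats Data frame with columns `chr`, `pos` (1-based) and
#'   `p`, one row per SNP.
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @param upstream,downstream Window extensions in bases (defaults
#'   110 kb / 40 kb).
#' @param exclude Optional [region_set()] of excluded regions.
#' @return A `gene_scores` data frame: `gene_id`, `raw_p` (best local p),
#'   `n_snps`, `gene_length`, `ld_proxy` (window SNP count unless genotype
#'   LD is supplied downstream).
#' @export
gene_scores <- function(summary_stats, genes, upstream = 110000,
                        downstream = 40000, exclude = NULL) {
  stopifnot(all(c("chr", "pos", "p") %in% names(summary_stats)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  minus <- genes$strand == "-"
  ws <- ifelse(minus, genes$start - downstream, genes$start - upstream)
  we <- ifelse(minus, genes$end + upstream, genes$end + downstream)
  win <- GenomicRanges::GRanges(
    as.character(genes$chrom),
    IRanges::IRanges(start = pmax(ws + 1, 1), end = we))
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "region_set"))
    body <- GenomicRanges::GRanges(
      as.character(genes$chrom),
      IRanges::IRanges(genes$start + 1, genes$end))
    drop <- GenomicRanges::countOverlaps(body, exclude$ranges) > 0
    genes <- genes[!drop, , drop = FALSE]
    win <- win[!drop]
  }
  snps <- GenomicRanges::GRanges(as.character(summary_stats$chr),
                                 IRanges::IRanges(summary_stats$pos,
                                                  summary_stats$pos))
  ov <- GenomicRanges::findOverlaps(win, snps)
  gi <- S4Vectors::queryHits(ov)
  pv <- summary_stats$p[S4Vectors::subjectHits(ov)]
  raw_p <- tapply(pv, factor(gi, levels = seq_len(nrow(genes))), min)
  n_snps <- tapply(pv, factor(gi, levels = seq_len(nrow(genes))), length)
  scored <- !is.na(raw_p)
  out <- data.frame(
    gene_id = genes$gene_id[scored],
    raw_p = as.numeric(raw_p[scored]),
    n_snps = as.integer(n_snps[scored]),
    gene_length = (genes$end - genes$start)[scored],
    ld_proxy = as.integer(n_snps[scored]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Adjust gene scores for confounders
#'
#' Regresses `-ln(raw_p)` on the confounders that inflate a best-local-SNP
#' score irrespective of true association -- gene length, SNP count in the
#' window and an LD proxy -- and ranks the residuals (largest residual =
#' rank `n` = most significant). Length and SNP count enter on the log scale,
#' under which the null expectation of the best-of-n score is linear; the LD
#' proxy enters as `log1p`. Collinear covariates are dropped with a warning.
#'
#' @param scores A `gene_scores` data frame ([gene_scores()]); at least 10
#'   scored genes.
#' @return The input with an `adjusted_score` column (average ranks on ties,
#'   so the result is independent of input order).
#' @export
adjust_scores <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("gene_id", "raw_p", "n_snps", "gene_length") %in%
                  names(scores)))
  if (nrow(scores) < 10L) stop("at least 10 scored genes are required")
  y <- -log(scores$raw_p)
  X <- cbind(log_length = log(pmax(scores$gene_length, 1)),
             log_n_snps = log(scores$n_snps),
             log_ld = log1p(scores$ld_proxy %||% scores$n_snps))
  fit <- stats::lm(y ~ X)
  if (anyNA(stats::coef(fit))) {
    warning("collinear confounder(s) dropped from the adjustment model")
  }
  scores$adjusted_score <- rank(stats::residuals(fit), ties.method = "average")
  scores
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then member gene
#'   ids, tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Percentile-cutoff gene-set enrichment by permutation
#'
#' For each gene set and each percentile cutoff, counts the member genes
#' whose adjusted score exceeds the cutoff percentile of all gene scores,
#' and compares that count with the same count in `n_perm` random gene sets
#' of identical size drawn without replacement from all scored genes:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`. Benjamini-Hochberg
#' q-values are computed across sets within each cutoff. Set members absent
#' from the scored genes are dropped; sets smaller than 2 after mapping are
#' skipped.
#'
#' @param scores A data frame with `gene_id` and `adjusted_score`
#'   ([adjust_scores()]).
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param cutoffs Percentile cutoffs (defaults 95 and 75).
#' @param n_perm Permutations per set/cutoff.
#' @param seed Integer seed.
#' @return An `enrichment_result` data frame: `set_name`,
#'   `cutoff_percentile`, `set_size`, `observed`, `expected`, `p_perm`,
#'   `fdr`.
#' @export
enrichment <- function(scores, gene_sets, cutoffs = c(95, 75),
                       n_perm = 10000L, seed = 1L) {
  stopifnot(all(c("gene_id", "adjusted_score") %in% names(scores)))
  s <- scores$adjusted_score
  names(s) <- scores$gene_id
  n_genes <- length(s)
  rows <- list()
  with_local_seed(seed, {
    for (cut in cutoffs) {
      thr <- stats::quantile(s, cut / 100, names = FALSE)
      above <- s > thr
      frac_above <- mean(above)
      for (set_name in names(gene_sets)) {
        members <- intersect(gene_sets[[set_name]], scores$gene_id)
        k <- length(members)
        if (k < 2L) next
        obs <- sum(above[members])
        null <- vapply(seq_len(n_perm), function(i)
          sum(above[sample.int(n_genes, k)]), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          set_name = set_name, cutoff_percentile = cut, set_size = k,
          observed = obs, expected = k * frac_above,
          p_perm = (1 + sum(null >= obs)) / (n_perm + 1),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable gene set (all smaller than 2 after mapping)")
  out$fdr <- NA_real_
  for (cut in unique(out$cutoff_percentile)) {
    i <- out$cutoff_percentile == cut
    out$fdr[i] <- stats::p.adjust(out$p_perm[i], method = "BH")
  }
  out <- out[order(out$cutoff_percentile, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
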