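#' Configuration for the forward Wright-Fisher haplotype simulator
#'
#' @param pop_size Diploid population size N (2N haplotypes evolve); >= 2.
#' @param n_generations Number of generations to simulate.
#' @param mutation_rate Per-site, per-generation mutation rate (>= 0).
#' @param seq_length Number of sites on the linear map.
#' @param selection_coeff Selection coefficient s (>= 0; 0 for neutrality).
#' @param selected_site Position (1..seq_length) of the selected site, or
#'   `NULL` for no focal selected mutation.
#' @param seed Integer seed.
#'
#' @return An object of class `wf_config`.
#' @export
wf_config <- function(pop_size, n_generations, mutation_rate, seq_length,
                      selection_coeff = 0, selected_site = NULL, seed = 1L) {
  if (pop_size < 2) stop("`pop_size` must be >= 2")
  if (mutation_rate < 0) stop("`mutation_rate` must be >= 0")
  if (selection_coeff < 0) stop("`selection_coeff` must be >= 0")
  if (!is.null(selected_site) &&
      (selected_site < 1 || selected_site > seq_length)) {
    stop("`selected_site` lies outside the simulated sequence")
  }
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 mutation_rate = mutation_rate,
                 seq_length = as.integer(seq_length),
                 selection_coeff = selection_coeff,
                 selected_site = selected_site,
                 seed = as.integer(seed)),
            class = "wf_config")
}

#' Construct a phased, polarised haplotype matrix
#'
#' @param haplotypes Binary matrix, one row per haplotype, one column per
#'   segregating site; 0 = ancestral allele, 1 = derived allele.
#' @param positions Strictly increasing site coordinates, one per column.
#' @param focal_site Column index of the focal site for haplotype-based
#'   statistics (may be `NA`).
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haplotypes, positions, focal_site = NA_integer_) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotype entries must be 0/1")
  if (ncol(haplotypes) != length(positions)) {
    stop("one position per site is required")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing")
  }
  structure(list(haplotypes = haplotypes, positions = as.numeric(positions),
                 focal_site = focal_site),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("Haplotype matrix: %d haplotypes x %d segregating sites\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  if (!is.na(x$focal_site)) {
    cat(sprintf("  focal site %d at position %g (derived freq %.3f)\n",
                x$focal_site, x$positions[x$focal_site],
                mean(x$haplotypes[, x$focal_site])))
  }
  invisible(x)
}

#' Forward Wright-Fisher simulation of polarised haplotypes
#'
#' Evolves 2N haplotypes by per-generation multinomial resampling with
#' infinite-sites mutation on a linear map (new mutations land on previously
#' monomorphic integer sites). With `selection_coeff > 0` the derived allele
#' at `selected_site` is injected at frequency 1/2N once the burn-in
#' (`selection_start` generations) has passed, re-injected whenever lost, and
#' carries multiplicative fitness `(1 + s)` per copy. Haplotypes are resampled
#' directly (no diploid pairing) and recombination is omitted, so EHH decay is
#' driven by mutation alone -- adequate for exercising haplotype statistics,
#' not for emulating realistic LD.
#'
#' @param config A [wf_config()] object.
#' @param selection_start Generation at which the selected mutation is
#'   injected (default: halfway through the run).
#'
#' @return A [haplotype_matrix()] of segregating sites (monomorphic sites
#'   dropped), with `focal_site` set to the selected site's column when it is
#'   still segregating.
#' @export
simulate_haplotypes <- function(config,
                                selection_start = config$n_generations %/% 2L) {
  stopifnot(inherits(config, "wf_config"))
  nh <- 2L * config$pop_size
  L <- config$seq_length
  sel <- config$selection_coeff > 0 && !is.null(config$selected_site)
  with_local_seed(config$seed, {
    # haplotypes as a logical matrix over currently-tracked sites
    hap <- matrix(FALSE, nrow = nh, ncol = 0L)
    pos <- integer(0)
    free_sites <- rep(TRUE, L)          # sites never yet mutated
    if (sel) free_sites[config$selected_site] <- FALSE
    mu_total <- config$mutation_rate * L

    for (gen in seq_len(config$n_generations)) {
      sel_col <- if (sel) match(config$selected_site, pos) else NA_integer_
      if (sel && gen >= selection_start) {
        if (is.na(sel_col)) {           # inject (or re-inject) the sweep allele
          hap <- cbind(hap, FALSE)
          pos <- c(pos, config$selected_site)
          ord <- order(pos)
          pos <- pos[ord]; hap <- hap[, ord, drop = FALSE]
          sel_col <- match(config$selected_site, pos)
          hap[sample.int(nh, 1L), sel_col] <- TRUE
        }
        w <- (1 + config$selection_coeff) ^ hap[, sel_col]
        idx <- sample.int(nh, nh, replace = TRUE, prob = w)
      } else {
        idx <- sample.int(nh, nh, replace = TRUE)
      }
      hap <- hap[idx, , drop = FALSE]

      n_mut <- stats::rpois(1L, nh * mu_total)
      if (n_mut > 0) {
        avail <- which(free_sites)
        n_mut <- min(n_mut, length(avail))
        if (n_mut > 0) {
          new_pos <- if (length(avail) == 1L) avail else
            sample(avail, n_mut)
          free_sites[new_pos] <- FALSE
          carriers <- sample.int(nh, n_mut, replace = TRUE)
          block <- matrix(FALSE, nrow = nh, ncol = n_mut)
          block[cbind(carriers, seq_len(n_mut))] <- TRUE
          hap <- cbind(hap, block)
          pos <- c(pos, new_pos)
          ord <- order(pos)
          pos <- pos[ord]; hap <- hap[, ord, drop = FALSE]
        }
      }

      if (ncol(hap)) {                  # drop fixed and lost sites
        cs <- colSums(hap)
        keep <- cs > 0L & cs < nh
        if (sel) {                      # retain the selected column while fixed
          sc <- match(config$selected_site, pos)   # (a lost one is re-injected)
          if (!is.na(sc)) keep[sc] <- cs[sc] > 0L
        }
        lost <- pos[cs == 0L]
        free_sites[setdiff(lost, config$selected_site %||% -1L)] <- TRUE
        hap <- hap[, keep, drop = FALSE]
        pos <- pos[keep]
      }
    }

    cs <- if (ncol(hap)) colSums(hap) else integer(0)
    keep <- cs > 0L & cs < nh
    hap <- hap[, keep, drop = FALSE]
    pos <- pos[keep]
    focal <- if (sel) match(config$selected_site, pos) else NA_integer_
    haplotype_matrix(hap * 1L, pos,
                     focal_site = if (is.na(focal)) NA_integer_ else focal)
  })
}
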