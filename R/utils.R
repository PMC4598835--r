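# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `code` under a temporarily seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_prob <- function(x, name, open = TRUE) {
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!all(is.finite(x)) || !ok) {
    stop(sprintf("`%s` must be %s", name,
                 if (open) "strictly inside (0, 1)" else "within [0, 1]"),
         call. = FALSE)
  }
  invisible(x)
}

# complement of A/C/G/T allele strings (vectorised, multi-base safe)
allele_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

is_palindromic <- function(ea, oa) toupper(ea) == allele_complement(toupper(oa))

fmt_or_ci <- function(or, lo, hi) sprintf("%.2f (%.2f-%.2f)", or, lo, hi)
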