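#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed (when non-`NULL`), evaluates `expr`, and restores the
#' caller's RNG state, so seeded internals (bootstraps, null simulations)
#' never perturb user-level random streams.
#'
#' @param seed Integer seed or `NULL` (evaluate with the current stream).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic stream of sub-seeds below 2^31, derived from a parent seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1, n)))
}

# two-sided normal p-value, floored at the smallest normalized double so
# extreme z-scores never underflow to an invalid p of exactly 0
.norm_pvalue <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}
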