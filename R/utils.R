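#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the generator seeded at `seed` and restores the caller's
#' RNG state afterwards, so that seeded helpers never perturb the global
#' random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index; keeps the
# result a valid 32-bit integer seed.
derive_seed <- function(master_seed, stream) {
  ((as.double(master_seed) %% 2147483647) * 48271 + 7919 * stream) %% 2147483647
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}
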