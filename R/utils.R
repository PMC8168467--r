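#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded functions do not perturb the global random
#' stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Single integer-valued seed, or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number or NULL")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stream-specific seed from a base seed
#'
#' Deterministic mapping used to give every subject / stage its own seed while
#' staying inside R's 32-bit integer range.
#'
#' @param seed Base seed.
#' @param stream Nonnegative integer stream index.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(stream)) %%
               2147483629)
}

# near-integer check for durations expressed on a time grid
is_whole <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol * max(1, abs(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
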