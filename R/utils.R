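#' Run code under a local RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state so seeded internals never disturb user-level
#' randomness.
#'
#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage gets its own
#' deterministic offset so stages are independently reproducible. Result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master seed (integer)
#' @param offset stage offset (small non-negative integer)
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(offset), length(offset) == 1L)
  as.integer((abs(as.numeric(seed)) + as.numeric(offset) * 1000003) %% 2147483647)
}

# canonical "u|v" keys for unordered node pairs (integer ids)
pair_keys <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
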