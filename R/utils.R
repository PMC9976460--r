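# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Euclidean distance matrix of bead coordinates
#' @param xyz n x 3 numeric matrix
#' @return n x n symmetric matrix with zero diagonal
#' @noRd
pair_dist_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

# Derive a stream of child seeds from one run seed, keeping every derived
# seed a valid 32-bit R integer. Deterministic and collision-poor enough
# for replicate/permutation bookkeeping.
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  base <- (as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483563
  as.integer((base + 7919 * seq_len(n)) %% 2147483562 + 1)
}

# Run an expression under a local RNG state so library code does not
# clobber the caller's .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(expr)
}

stop_sc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_sc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
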