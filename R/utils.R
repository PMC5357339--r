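# internal helpers shared across modules

# run expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic seed ledger: every stage of a pipeline run draws its own
#' seed from the master seed and a fixed offset, so a single integer
#' reproduces the whole run. Results stay within 32-bit integer range.
#'
#' @param master_seed integer master seed.
#' @param offset fixed integer offset identifying the stage.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master_seed, offset) {
  as.integer((as.numeric(master_seed) * 97 + offset) %% 2147483587L + 1L)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
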