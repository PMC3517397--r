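## Reproducible substreams. Every source of randomness in the package is a
## L'Ecuyer-CMRG stream addressed by (baseSeed, streamId): stream 0 is the
## state right after set.seed(baseSeed, kind = "L'Ecuyer-CMRG"), stream i is
## obtained by advancing i times with parallel::nextRNGStream(). Streams are
## therefore independent of how work is scheduled across workers.

#' RNG stream state for (baseSeed, streamId)
#'
#' @param baseSeed Integer base seed (< 2^31).
#' @param streamId Non-negative integer stream index.
#' @return A `.Random.seed`-compatible integer vector.
#' @examples
#' s <- rngStream(11, 3)
#' @export
rngStream <- function(baseSeed, streamId = 0L) {
  stopifnot(is.numeric(baseSeed), length(baseSeed) == 1L,
            is.numeric(streamId), streamId >= 0)
  state <- local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(baseSeed), kind = "L'Ecuyer-CMRG")
    get(".Random.seed", globalenv())
  })
  for (i in seq_len(streamId)) state <- parallel::nextRNGStream(state)
  state
}

#' Evaluate an expression under a given RNG stream
#'
#' Sets `.Random.seed` to the stream for `(baseSeed, streamId)`, evaluates
#' `expr`, and restores the caller's RNG state afterwards.
#'
#' @param baseSeed Integer base seed.
#' @param streamId Stream index.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @examples
#' withStream(42, 1, rnorm(3))
#' @export
withStream <- function(baseSeed, streamId, expr) {
  state <- rngStream(baseSeed, streamId)
  withRNGState(state, expr)
}

## Evaluate expr with .Random.seed = state; returns list(value, state) when
## capture = TRUE so callers can persist the advanced stream.
withRNGState <- function(state, expr, capture = FALSE) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state, globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  value <- expr
  if (capture)
    list(value = value, state = get(".Random.seed", globalenv()))
  else value
}

#' Derive a reproducible sub-seed
#'
#' Maps a base seed and a small integer key to another valid 32-bit seed;
#' used to give nested runs (e.g. per-fold samplers inside a pipeline)
#' distinct but reproducible base seeds.
#'
#' @param baseSeed Integer base seed.
#' @param key Non-negative integer key.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(baseSeed, key) {
  stopifnot(is.numeric(baseSeed), is.numeric(key), key >= 0)
  as.integer((as.numeric(baseSeed) %% 2147483647 + 1000003 * (key + 1)) %%
               2147483647)
}
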