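#' Derive a reproducible child seed for a named random stream
#'
#' Ensemble construction draws from several independent streams (one for the
#' mitochondrial levels, one per protein). Deriving a deterministic child seed
#' per stream from one global seed means adding or removing a protein does not
#' perturb the draws of the other streams.
#'
#' @param seed Integer global seed.
#' @param stream Character stream label (e.g. a protein name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  h <- 0
  for (v in utf8ToInt(stream)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
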