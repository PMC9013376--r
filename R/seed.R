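#' Derive a named sub-seed from a master seed
#'
#' A single master seed fans out deterministically to the independent random
#' streams of a run (phantom geometry, k-space noise, weight initialisation,
#' batch shuffling), so that any stage can be rerun in isolation and
#' reproduce its output exactly.  The derivation is a small multiplicative
#' hash of the stream name folded into the master seed, reduced modulo
#' 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param name Character stream name, e.g. `"phantom"`, `"noise"`.
#' @param index Optional non-negative integer distinguishing items within a
#'   stream (e.g. the image number).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' seed_stream(7, "noise", 3)
#' @export
seed_stream <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m + 1) %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  h <- (h * 48271) %% m # Lehmer step to decorrelate adjacent indices
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression with a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library functions never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
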