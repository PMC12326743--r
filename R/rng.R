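#' Seeded random-number substreams
#'
#' All stochastic components (episode sampling, augmentation draws, weight
#' initialization, client partitioning, synthetic generation) consume an
#' explicit stream object so that a single root seed reproduces a whole run
#' bit-for-bit while keeping the substreams independent of call order across
#' components.
#'
#' A stream wraps a saved `.Random.seed` state; [with_rng()] temporarily
#' installs it, evaluates an expression, and stores the advanced state back,
#' leaving the global RNG untouched for the caller.
#'
#' @param seed Integer seed (kept within 32-bit range).
#' @return An object of class `rng_stream`.
#' @examples
#' r <- rng_stream(7)
#' a <- with_rng(r, runif(3))
#' b <- with_rng(rng_stream(7), runif(3))
#' stopifnot(identical(a, b))
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param rng An [rng_stream()].
#' @param code Expression using R's RNG.
#' @return The value of `code`.
#' @export
with_rng <- function(rng, code) {
  stopifnot(inherits(rng, "rng_stream"))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  if (is.null(rng$state)) set.seed(rng$seed) else
    assign(".Random.seed", rng$state, envir = genv)
  on.exit({
    rng$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (had) assign(".Random.seed", old, envir = genv) else
      rm(".Random.seed", envir = genv)
  })
  code
}

#' Derive a named sub-seed from a root seed
#'
#' Deterministic 32-bit mixing of a root seed and a string key, so each
#' component (e.g. `"sampling"`, `"augment"`, client ids) gets its own
#' reproducible stream.
#'
#' @param seed Integer root seed.
#' @param key Character key naming the substream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}
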