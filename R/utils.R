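# Internal helpers: seeded evaluation and reproducible child streams.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state. With `seed = NULL` the code runs on the current
#' stream (no save/restore), so functions compose with an outer seed.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a root seed
#'
#' Lehmer-style mixing: `(root * 48271 + r) mod (2^31 - 1)`. Exact in
#' double precision for root < 2^31, so replicate `r` of an ensemble gets
#' the same stream regardless of evaluation order or parallelism.
#'
#' @param seed root seed (integer-valued scalar).
#' @param r replicate index (>= 0).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
child_seed <- function(seed, r) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(r), all(r >= 0))
  m <- 2147483647
  s <- (abs(seed) %% m) * 48271 %% m
  as.integer((s + r) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
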