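# Internal helpers.

# Evaluate fun() under a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the current stream is used (and advanced).
eval_with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fun()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)
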