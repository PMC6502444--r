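`%||%` <- function(a, b) if (is.null(a)) b else a

ct_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ct_error")))
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
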