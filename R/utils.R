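# Internal helpers: error conditions and seeded evaluation.

tc_stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("tc_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

tc_stop_io <- function(msg, ...) {
  stop(structure(
    class = c("tc_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded functions compose predictably.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
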