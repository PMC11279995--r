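# Internal helpers: structured conditions and local RNG scoping.

opivi_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "opivi_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level randomness. seed = NULL runs code under the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    opivi_error("`seed` must be a single finite number.", "opivi_bad_seed")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# mean of x robust to length-0
finite_or_error <- function(x, what) {
  if (any(!is.finite(x))) {
    opivi_error(sprintf("non-finite values in %s", what), "opivi_nonfinite")
  }
  invisible(x)
}
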