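#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @useDynLib mimicry, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller-visible state afterwards. All exported stochastic functions
# take explicit seeds and route through here: no global random state leaks.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

mim_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "mimicry_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
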