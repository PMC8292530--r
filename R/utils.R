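`%||%` <- function(a, b) if (is.null(a)) b else a

clip255 <- function(x) pmin(pmax(x, 0), 255)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Deterministic 31-bit hash of a string
#'
#' Polynomial rolling hash used to key per-slide random streams, so that a
#' slide's pixels depend only on (master seed, slide id) and not on how many
#' other slides exist in the cohort.
#' @param s a character scalar
#' @return an integer in `[0, 2^31 - 2]`
#' @keywords internal
hash_string <- function(s) {
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Combine a master seed with a string key into a stream seed < 2^31.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + hash_string(key)) %% 2147483647)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library functions never perturb the
#' caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}
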