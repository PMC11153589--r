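# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded package
#' internals never perturb the user's random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("ehrisk_config_error", "error")))
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("'%s' must contain probabilities in [0, 1]", name)
  invisible(x)
}

assert_dist <- function(p, name, tol = 1e-9) {
  assert_prob(p, name)
  if (abs(sum(p) - 1) > tol)
    stop_config("categorical distribution '%s' must sum to 1 (got %.12f)", name, sum(p))
  invisible(p)
}

# Stable seed derivation: fold a parent seed and a stream index into a
# 31-bit integer so derived seeds stay valid R integers.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647L)
}
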