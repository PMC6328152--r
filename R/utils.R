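#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All stochastic operations in the package draw from their own stream, seeded
#' by hashing a root seed together with a purpose label (and, where relevant,
#' an entity id such as a session id). Adding new sessions or participants
#' therefore never perturbs draws already made for existing ones.
#'
#' @param seed integer root seed.
#' @param label character label identifying the stream.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derived_seed(1L, "winner:S01")
derived_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    # 31-ary polynomial rolling hash; doubles stay exact below 2^53
    h <- (h * 31 + code) %% m
  }
  # one multiplicative scramble so nearby labels decorrelate
  h <- (h * 48271) %% m
  as.integer(h) + 1L
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG with `seed`, runs `expr`, and restores the caller's RNG state
#' afterwards, so package internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# significance stars at the 10 / 5 / 1 % two-sided levels
p_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
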