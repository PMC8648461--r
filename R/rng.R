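#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator with
#' `seed`, evaluates `expr`, and restores the previous state, so seeded
#' generators never perturb the session RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a run seed
#'
#' Deterministic splitting of one run seed into per-patient / per-timepoint
#' seeds via a Lehmer step modulo the Mersenne prime 2^31 - 1, keeping every
#' derived seed a valid 32-bit R integer.
#'
#' @param seed parent integer seed.
#' @param k non-negative integer index of the child stream.
#' @return a single integer in [1, 2^31 - 2].
#' @keywords internal
child_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m + m) %% m
  for (i in seq_len(as.integer(k) %% 64L + 1L)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(if (s == 0) 1 else s)
}
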