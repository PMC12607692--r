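# Internal helpers: deterministic seed derivation and scoped RNG use.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a stage label into an offset so that every pipeline stage draws
#' from its own reproducible stream while a single master seed controls the
#' whole run. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"beta"`, `"dim2"`).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(master)) * 1009 + h * 97) %% 2147483647)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# stopifnot() with a formatted message
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}
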