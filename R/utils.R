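# Internal helpers shared across modules.

# Deterministically derive a child seed from a parent seed and a salt.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(salt)) {
    salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807 + 12345) %%
               2147483647)
}

# Run an expression under a local RNG state so library code does not
# clobber the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_mod <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
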