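# Internal RNG helpers: run `expr` under `seed` and restore the caller's RNG
# state afterwards, so no exported function leaks global RNG side effects.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483629)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
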