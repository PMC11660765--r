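#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a subsidiary 32-bit seed from a run-level seed and a counter, so
## every stochastic stage of a run is reproducible from one integer.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  as.integer((as.double(seed) + 104729 * as.double(counter)) %% 2147483647)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Full-precision, locale-independent number formatting for the CSV
## writers: round-trips doubles exactly and is byte-stable across runs.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

is_flag_true <- function(x) isTRUE(x) || identical(x, "true") || identical(x, "TRUE")
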