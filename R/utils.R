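# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(i)) %% 2147483629)
}

stop_kmsmote <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
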