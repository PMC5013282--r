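# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic stages derive their seeds from
# one top-level value through this helper so runs are reproducible.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from the run seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

# Locale-independent, stable ordering for character keys.
stable_order <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = digits, format = "g")))
}
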