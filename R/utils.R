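# Internal helpers: seeded evaluation and stable per-subject RNG streams.

# Run `expr` under a given RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stable 31-bit polynomial hash of a string; independent of R's RNG and of
# insertion order, so per-subject streams never depend on generation order.
hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

subject_seed <- function(master_seed, subject_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 + hash_string(subject_id)) %%
               2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower)
    stop(sprintf("`%s` must be a finite number >= %s", name, format(lower)),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
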