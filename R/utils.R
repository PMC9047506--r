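# Internal helpers: deterministic seed management.
#
# One user-facing integer seed is split into independent per-stage seeds so
# each stage is reproducible on its own and insensitive to what ran before.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from (seed, tag); tag may be a string or integers.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
seed_child <- function(seed, tag) {
  m <- 2147483647
  h <- if (is.character(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) else sum(as.numeric(tag) * seq_along(tag))
  as.integer((((as.numeric(seed) %% m) * 48271) %% m + (h %% m)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) stopf("'%s' must be strictly positive", name)
  invisible(x)
}
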