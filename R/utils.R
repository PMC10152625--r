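# Internal helpers: seeding policy and small utilities.

# Evaluate expr with the global RNG temporarily seeded; the caller's RNG
# state is restored afterwards.  seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic substream derivation: mixes a master seed with integer
# indices into a new seed below 2^31 - 1.  Linear-congruential mixing in
# double precision (all intermediates < 2^53, so exact).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(abs(seed) %% 2147483647)
  for (k in idx) {
    x <- (x * 69069 + (as.double(k) %% 2147483647) * 1234567 + 12345) %%
      2147483647
  }
  as.integer(max(x, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_binary_outcome <- function(y) {
  if (anyNA(y)) stop_("outcome contains missing values")
  if (!all(y %in% c(0, 1))) stop_("outcome must contain only 0 and 1")
  if (length(unique(y)) < 2L)
    stop_("degenerate input: outcome contains a single class")
  invisible(TRUE)
}
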