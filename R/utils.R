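# Internal helpers: seeded evaluation without clobbering the caller's RNG
# state, sub-seed derivation, and byte/hex conversions.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed), restoring the global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive an independent 31-bit sub-seed from a master seed
# and a stream label, via SHA-256.  Keeps protocol roles, permutations and
# key draws on separate reproducible streams.
derive_seed <- function(seed, label) {
  h <- .sha256_hex(charToRaw(sprintf("pprisk:%s:%s", format(seed), label)))
  (strtoi(substr(h, 1L, 7L), base = 16L) %% 2147483646L) + 1L
}

hex_to_raw <- function(hex) {
  stopifnot(nchar(hex) %% 2 == 0)
  as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
                base = 16L))
}

raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

# n random bytes from R's RNG (stream-respecting, reproducible under seeds)
random_bytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
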