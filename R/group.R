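# Algebraic setting for the commutative cipher: a prime modulus p with a
# prime-order subgroup of order q, q | p - 1.  All big integers are held as
# decimal strings and manipulated through the OpenSSL BIGNUM bindings in
# src/bignum.cpp.

#' Construct or validate group parameters
#'
#' Defines the prime-order subgroup in which the commutative
#' (Pohlig--Hellman style) cipher operates: a prime modulus `p`, a prime
#' subgroup order `q` with `q | p - 1`, and the cofactor `(p - 1) / q`.
#' Both primes are re-checked with a Miller--Rabin test on construction, so
#' a `group_params` object is always internally consistent.
#'
#' @param p Prime modulus, as an integer or decimal string.
#' @param q Prime subgroup order, as an integer or decimal string.
#' @param hash Hash algorithm used downstream for quasi-identifiers and
#'   hash-to-group; only `"sha256"` is supported, the field is recorded in
#'   serialized parameter files for reproducibility.
#' @return An object of class `group_params` with fields `p`, `q`,
#'   `cofactor` (decimal strings) and `hash`.
#' @examples
#' gp <- group_params(23, 11)  # toy group: 11 divides 22
#' gp$cofactor
#' @seealso [generate_group_params()] to search for fresh parameters.
#' @export
group_params <- function(p, q, hash = "sha256") {
  p <- as_decimal(p)
  q <- as_decimal(q)
  abort_if(!identical(hash, "sha256"), "unsupported hash '%s'", hash)
  abort_if(!.bn_is_prime(p), "p = %s is not prime", p)
  abort_if(!.bn_is_prime(q), "q = %s is not prime", q)
  pm1 <- sub_one(p)
  abort_if(.bn_mod(pm1, q) != "0", "q does not divide p - 1")
  cofactor <- bn_div_exact(pm1, q)
  structure(list(p = p, q = q, cofactor = cofactor, hash = hash),
            class = "group_params")
}

#' Generate group parameters deterministically
#'
#' Searches for a `q_bits`-bit prime `q` and a `p_bits`-bit prime
#' `p = c * q + 1` (Schnorr group).  Candidates are drawn from a SHA-256
#' counter stream keyed by `seed`, so the same arguments always produce
#' the same group.  The production default is a 2048-bit modulus with a
#' 160-bit subgroup; bit lengths down to 16 are accepted so that tests can
#' use toy groups.
#'
#' @param p_bits Bit length of the modulus (default 2048).
#' @param q_bits Bit length of the subgroup order (default 160).
#' @param seed Integer seed; mandatory, drives the candidate stream.
#' @param max_candidates Bound on candidates tried per prime before the
#'   search is declared infeasible.
#' @return A `group_params` object.
#' @examples
#' gp <- generate_group_params(64, 32, seed = 7)
#' identical(gp, generate_group_params(64, 32, seed = 7))
#' @export
generate_group_params <- function(p_bits = 2048, q_bits = 160, seed,
                                  max_candidates = 100000L) {
  abort_if(missing(seed), "a seed is required for reproducible generation")
  abort_if(q_bits >= p_bits || q_bits < 16,
           "require 16 <= q_bits < p_bits (got %d, %d)", q_bits, p_bits)
  seed_bytes <- charToRaw(sprintf("pprisk-group:%d:%d:%s", p_bits, q_bits,
                                  format(seed)))
  raw <- .gen_group_params(as.integer(p_bits), as.integer(q_bits), seed_bytes,
                           as.integer(max_candidates))
  group_params(raw$p, raw$q)
}

#' @export
print.group_params <- function(x, ...) {
  cat(sprintf("<group_params> |p| = %d bit, |q| = %d bit, hash = %s\n",
              .bn_num_bits(x$p), .bn_num_bits(x$q), x$hash))
  invisible(x)
}

#' Draw a commutative-cipher key
#'
#' A key is a secret exponent `u` uniform in `[1, q - 1]`; encryption is
#' `x -> x^u mod p`.  Two parties' keys commute because exponentiation in
#' an abelian group does.
#'
#' @param params A [group_params()] object.
#' @param seed Optional integer seed for a reproducible draw; when `NULL`
#'   the current RNG stream is used.
#' @param exponent Supply a fixed exponent directly (integer or decimal
#'   string) instead of drawing one.
#' @return An object of class `commutative_key` with field `exponent`.
#' @export
commutative_key <- function(params, seed = NULL, exponent = NULL) {
  stopifnot(inherits(params, "group_params"))
  if (is.null(exponent)) {
    nbytes <- ceiling(.bn_num_bits(params$q) / 8) + 8L  # oversample, reduce
    bytes <- if (is.null(seed)) random_bytes(nbytes)
             else with_seed(seed, random_bytes(nbytes))
    exponent <- .bn_bytes_to_exponent(bytes, params$q)
  } else {
    exponent <- as_decimal(exponent)
    abort_if(.bn_cmp(exponent, "1") < 0 ||
             .bn_cmp(exponent, sub_one(params$q)) > 0,
             "exponent outside [1, q - 1]")
  }
  structure(list(exponent = exponent), class = "commutative_key")
}

#' @export
print.commutative_key <- function(x, ...) {
  cat(sprintf("<commutative_key> %d-bit secret exponent\n",
              .bn_num_bits(x$exponent)))
  invisible(x)
}

#' Hash a byte string onto the prime-order subgroup
#'
#' Realizes `H(m)` of the commutative cipher `f(m) = H(m)^u mod p`:
#' the SHA-256 digest of `message || counter` (counter a 4-byte big-endian
#' integer starting at 0) is reduced mod `p` and raised to the cofactor
#' `(p - 1) / q`, which lands it in the order-`q` subgroup; the counter is
#' incremented until the result is not the identity.  Deterministic, so
#' both parties map equal messages to equal elements.
#'
#' @param messages A raw vector, a character vector, or a list of raw
#'   vectors; each entry is hashed independently.
#' @param params A [group_params()] object.
#' @return Character vector of group elements (decimal strings).
#' @examples
#' gp <- group_params(23, 11)
#' hash_to_group("alice", gp)
#' @export
hash_to_group <- function(messages, params) {
  stopifnot(inherits(params, "group_params"))
  msgs <- normalize_messages(messages)
  abort_if(any(lengths(msgs) == 0), "messages must be non-empty")
  .hash_to_group(msgs, params$p, params$cofactor)
}

#' Apply one layer of the commutative cipher
#'
#' `commute_encrypt` raises each group element to the key's secret
#' exponent mod `p`; `commute_decrypt` applies the inverse exponent mod
#' `q` and undoes it.  For independent keys `u`, `v`:
#' `f(g(x)) = g(f(x))` — the property the intersection protocol relies on.
#'
#' @param elements Character vector of group elements (decimal strings).
#' @param key A [commutative_key()].
#' @param params A [group_params()] object.
#' @return Character vector of transformed group elements.
#' @examples
#' gp <- group_params(23, 11)
#' u <- commutative_key(gp, seed = 1)
#' e <- hash_to_group("msg", gp)
#' commute_decrypt(commute_encrypt(e, u, gp), u, gp) == e
#' @export
commute_encrypt <- function(elements, key, params) {
  stopifnot(inherits(key, "commutative_key"), inherits(params, "group_params"))
  validate_elements(elements, params)
  .bn_mod_exp(elements, key$exponent, params$p)
}

#' @rdname commute_encrypt
#' @export
commute_decrypt <- function(elements, key, params) {
  stopifnot(inherits(key, "commutative_key"), inherits(params, "group_params"))
  validate_elements(elements, params)
  inv <- .bn_mod_inverse(key$exponent, params$q)
  .bn_mod_exp(elements, inv, params$p)
}

#' Test subgroup membership
#'
#' An element is valid when it lies in `[1, p - 1]` and has order dividing
#' `q`, i.e. `x^q mod p = 1`.
#'
#' @inheritParams commute_encrypt
#' @return Logical vector.
#' @export
is_group_element <- function(elements, params) {
  stopifnot(inherits(params, "group_params"))
  in_range <- vapply(elements, function(e) {
    .bn_cmp(e, "0") > 0 && .bn_cmp(e, params$p) < 0
  }, logical(1), USE.NAMES = FALSE)
  ok <- in_range
  if (any(in_range)) {
    pow <- .bn_mod_exp(elements[in_range], params$q, params$p)
    ok[in_range] <- pow == "1"
  }
  ok
}

#' Read or write group parameters as JSON
#'
#' The on-disk form stores `p`, `q`, `cofactor` as decimal strings plus the
#' hash algorithm name, so parameter files are portable across platforms
#' and word sizes.
#'
#' @param params A [group_params()] object.
#' @param path File path.
#' @return `write_group_params` returns `path` invisibly;
#'   `read_group_params` returns a validated `group_params`.
#' @export
write_group_params <- function(params, path) {
  stopifnot(inherits(params, "group_params"))
  jsonlite::write_json(
    list(p = params$p, q = params$q, cofactor = params$cofactor,
         hash = params$hash),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_group_params
#' @export
read_group_params <- function(path) {
  x <- jsonlite::read_json(path)
  gp <- group_params(x$p, x$q, hash = x$hash %||% "sha256")
  abort_if(!identical(gp$cofactor, x$cofactor),
           "cofactor in file disagrees with (p - 1) / q")
  gp
}

# ---- internal ----

as_decimal <- function(x) {
  if (inherits(x, "numeric") || inherits(x, "integer")) {
    abort_if(!is_count(x), "expected a non-negative integer")
    x <- format(x, scientific = FALSE)
  }
  abort_if(!grepl("^[0-9]+$", x), "expected a decimal integer string")
  sub("^0+(?=.)", "", x, perl = TRUE)
}

sub_one <- function(dec) .bn_sub(dec, "1")

bn_div_exact <- function(a, b) .bn_div(a, b)

normalize_messages <- function(messages) {
  if (is.raw(messages)) return(list(messages))
  if (is.character(messages)) return(lapply(messages, charToRaw))
  if (is.list(messages)) {
    stopifnot(all(vapply(messages, is.raw, logical(1))))
    return(messages)
  }
  stop("messages must be raw, character, or a list of raw vectors")
}

validate_elements <- function(elements, params) {
  abort_if(!is.character(elements) || length(elements) == 0,
           "elements must be a non-empty character vector")
  bad <- !grepl("^[0-9]+$", elements)
  abort_if(any(bad), "malformed ciphertext at position %d",
           which(bad)[1])
  oob <- vapply(elements, function(e) {
    .bn_cmp(e, "0") <= 0 || .bn_cmp(e, params$p) >= 0
  }, logical(1), USE.NAMES = FALSE)
  abort_if(any(oob), "element outside [1, p - 1] at position %d",
           which(oob)[1])
  invisible(TRUE)
}
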