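# Private set intersection (cardinality) via commutative encryption.
#
# Round structure between Alice (set X) and Bob (set Y):
#   1. alice -> bob : { H(x)^u }   shuffled          (layer 1)
#   2. bob -> alice : { H(x)^uv }  re-shuffled       (layer 2)
#      (in elements mode the pairs (H(x)^u, H(x)^uv) stay aligned so that
#       Alice can map matches back to her own inputs)
#   3. bob -> alice : { H(y)^v }   shuffled          (layer 1)
# Alice then computes { H(y)^vu } locally and matches the two layer-2
# multisets as sorted sets.  Only blinded group elements and set sizes
# ever appear on the wire.

#' Private set intersection cardinality
#'
#' Computes `|set_a intersect set_b|` between two parties using the
#' commutative cipher `x -> x^u mod p`: equal inputs end up as equal
#' double-encrypted elements regardless of the order in which the two
#' secret exponents were applied.  Every outgoing element list is passed
#' through a seeded Fisher--Yates shuffle so transcript positions carry no
#' linkage information.
#'
#' @param set_a,set_b Character vectors of identifiers (deduplicated;
#'   typically hex [quasi_id()] digests).
#' @param params A [group_params()] object.
#' @param seed_a,seed_b Integer seeds for Alice's and Bob's secret keys and
#'   permutations; the protocol is fully deterministic given both.
#' @return A list of class `psi_result` with elements `count` (the
#'   cardinality), `transcript` (list of wire rounds, see
#'   [write_transcript()]), and `sizes` (the set sizes each party learns).
#' @examples
#' gp <- group_params(2027, 1013)
#' psi_cardinality(c("a", "b", "c"), c("b", "c", "d"), gp, 1, 2)$count
#' @export
psi_cardinality <- function(set_a, set_b, params, seed_a, seed_b) {
  psi_session(set_a, set_b, params, seed_a, seed_b, elements = FALSE)
}

#' Private set intersection with element recovery
#'
#' Variant of [psi_cardinality()] in which the second round sends the
#' double encryption together with the single-encrypted ciphertext, so the
#' initiating party (Alice) — and only Alice — learns which of her inputs
#' lie in the intersection.
#'
#' @inheritParams psi_cardinality
#' @return A `psi_result` whose `elements` field holds the common
#'   identifiers (a subset of `set_a`).
#' @export
psi_elements <- function(set_a, set_b, params, seed_a, seed_b) {
  psi_session(set_a, set_b, params, seed_a, seed_b, elements = TRUE)
}

psi_session <- function(set_a, set_b, params, seed_a, seed_b,
                        elements = FALSE) {
  stopifnot(inherits(params, "group_params"))
  abort_if(anyDuplicated(set_a) > 0, "set_a contains duplicates")
  abort_if(anyDuplicated(set_b) > 0, "set_b contains duplicates")

  key_a <- commutative_key(params, seed = derive_seed(seed_a, "key"))
  key_b <- commutative_key(params, seed = derive_seed(seed_b, "key"))
  transcript <- list()

  # round 1: Alice blinds and sends her set
  ea <- encrypt_set(set_a, key_a, params)
  perm1 <- seeded_permutation(length(ea), derive_seed(seed_a, "perm1"))
  ea_sent <- ea[perm1]
  transcript[[1]] <- wire_round("alice", 1L, ea_sent)

  # round 2: Bob adds his layer
  eab <- if (length(ea_sent)) commute_encrypt(ea_sent, key_b, params)
         else character(0)
  perm2 <- seeded_permutation(length(eab), derive_seed(seed_b, "perm2"))
  if (elements) {
    transcript[[2]] <- wire_round("bob", 2L, eab[perm2],
                                  paired_with = ea_sent[perm2])
  } else {
    transcript[[2]] <- wire_round("bob", 2L, eab[perm2])
  }

  # round 3: Bob blinds and sends his own set
  eb <- encrypt_set(set_b, key_b, params)
  perm3 <- seeded_permutation(length(eb), derive_seed(seed_b, "perm3"))
  eb_sent <- eb[perm3]
  transcript[[3]] <- wire_round("bob", 1L, eb_sent)

  # Alice completes both layers locally and matches as sets
  eba <- if (length(eb_sent)) commute_encrypt(eb_sent, key_a, params)
         else character(0)
  common <- intersect(transcript[[2]]$elements, eba)

  out <- list(count = length(common), transcript = transcript,
              sizes = c(a = length(set_a), b = length(set_b)))
  if (elements) {
    # map double-encryptions back to Alice's inputs via the aligned pairs
    idx <- match(transcript[[2]]$paired_with, ea)
    back <- setNames(set_a[idx], transcript[[2]]$elements)
    out$elements <- unname(back[common])
  }
  class(out) <- "psi_result"
  out
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> |A| = %d, |B| = %d, |intersection| = %d\n",
              x$sizes[["a"]], x$sizes[["b"]], x$count))
  invisible(x)
}

#' Serialize a protocol transcript as JSON lines
#'
#' One wire round per line: fields `role` (`alice`/`bob`), `layer` (1 =
#' single-, 2 = double-encrypted), `n`, `elements` (decimal strings), and
#' optionally `class` (exposure-class label) and `paired_with`.
#'
#' @param transcript A transcript list as found in `psi_result$transcript`
#'   or `protocol_result$transcript`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  lines <- vapply(transcript, function(rd) {
    jsonlite::toJSON(rd[!vapply(rd, is.null, logical(1))],
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x$elements <- as.character(x$elements)
    x
  })
}

# ---- internal ----

encrypt_set <- function(ids, key, params) {
  if (length(ids) == 0) return(character(0))
  commute_encrypt(hash_to_group(ids, params), key, params)
}

seeded_permutation <- function(n, seed) {
  if (n == 0) return(integer(0))
  with_seed(seed, sample.int(n, n))
}

wire_round <- function(role, layer, elements, class = NULL,
                       paired_with = NULL) {
  list(role = role, layer = layer, n = length(elements),
       class = class, elements = as.character(elements),
       paired_with = paired_with)
}
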