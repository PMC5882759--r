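# Two-party orchestration: Alice (case registry, set X of quasi-IDs) and
# Bob (survey partitioned into exposure classes Y_1..Y_q) jointly compute
# the stratified relative-risk table.  One commutative key pair (u, v) is
# used for the whole run; Alice's blinded set is sent once, Bob answers
# with its double encryption plus one blinded message per class, and
# Alice completes the second layer locally to count each |X inter Y_p|.
# Only blinded group elements and set sizes cross the wire.

#' Run the privacy-preserving stratified relative-risk protocol
#'
#' End-to-end execution of both roles in-process: records are
#' canonicalized and hashed into quasi-identifiers ([quasi_id_table()]),
#' linked per exposure class through PSI cardinality, and the resulting
#' counts fed to [stratified_rr()].  Deterministic given `seed`.
#'
#' @param alice_records Data frame: the case registry (attribute columns
#'   per the schema).
#' @param bob_records Data frame: the survey; must carry the exposure
#'   class label in `class_column`.
#' @param option An [attribute_option()] shared by both parties.
#' @param params A [group_params()] object shared by both parties.
#' @param seed Integer master seed (keys and permutations are derived
#'   from it on separate streams).
#' @param reference_label Reference exposure class; defaults to the first
#'   class in `bob_records` order.
#' @param class_column Name of Bob's exposure-class column.
#' @param chi2 Chi-squared variant passed to [stratified_rr()].
#' @param alpha Significance level.
#' @return An object of class `protocol_result`: `counts` (per-class
#'   `a_p`, `b_p`), `result` (the [stratified_rr()] table, or a
#'   placeholder with `NA` RRs when the reference class has no linked
#'   cases), `transcript`, `leakage` (the declared leakage surface), and
#'   `sizes`.
#' @examples
#' \donttest{
#' gp <- generate_group_params(64, 32, seed = 11)
#' cohort <- generate_from_counts(
#'   data.frame(label = c("L", "H"), cases = c(3, 1), noncases = c(5, 7)),
#'   seed = 5)
#' run_protocol(cohort$alice, cohort$bob, standard_option("D"), gp, seed = 9)
#' }
#' @export
run_protocol <- function(alice_records, bob_records, option, params, seed,
                         reference_label = NULL,
                         class_column = "exposure_class",
                         chi2 = c("uncorrected", "yates"), alpha = 0.05) {
  chi2 <- match.arg(chi2)
  stopifnot(inherits(option, "attribute_option"),
            inherits(params, "group_params"))
  abort_if(!class_column %in% names(bob_records),
           "bob_records lacks class column '%s'", class_column)

  x_ids <- unique(quasi_id_table(alice_records, option))
  labels <- unique(as.character(bob_records[[class_column]]))
  y_sets <- lapply(labels, function(l) {
    unique(quasi_id_table(
      bob_records[bob_records[[class_column]] == l, , drop = FALSE], option))
  })
  names(y_sets) <- labels
  check_disjoint(y_sets)
  reference_label <- reference_label %||% labels[1]
  abort_if(!reference_label %in% labels,
           "reference class '%s' absent from survey", reference_label)

  key_a <- commutative_key(params, seed = derive_seed(seed, "alice-key"))
  key_b <- commutative_key(params, seed = derive_seed(seed, "bob-key"))
  transcript <- list()

  # Alice -> Bob: blinded case set, once for the whole run
  ea <- if (length(x_ids)) {
    commute_encrypt(hash_to_group(x_ids, params), key_a, params)
  } else character(0)
  ea_sent <- ea[seeded_permutation(length(ea),
                                   derive_seed(seed, "alice-perm"))]
  transcript[[length(transcript) + 1]] <- wire_round("alice", 1L, ea_sent)

  # Bob -> Alice: double-encrypted case set
  eab <- if (length(ea_sent)) commute_encrypt(ea_sent, key_b, params)
         else character(0)
  eab_sent <- eab[seeded_permutation(length(eab),
                                     derive_seed(seed, "bob-perm-x"))]
  transcript[[length(transcript) + 1]] <- wire_round("bob", 2L, eab_sent)

  # Bob -> Alice: one blinded message per exposure class
  counts <- data.frame(label = labels, cases = 0L, noncases = 0L,
                       size = vapply(y_sets, length, integer(1)))
  for (l in labels) {
    yb <- if (length(y_sets[[l]])) {
      commute_encrypt(hash_to_group(y_sets[[l]], params), key_b, params)
    } else character(0)
    yb_sent <- yb[seeded_permutation(
      length(yb), derive_seed(seed, paste0("bob-perm-", l)))]
    transcript[[length(transcript) + 1]] <-
      wire_round("bob", 1L, yb_sent, class = l)
    # Alice closes the second layer and matches as sets
    yba <- if (length(yb_sent)) commute_encrypt(yb_sent, key_a, params)
           else character(0)
    a_p <- length(intersect(eab_sent, yba))
    counts$cases[counts$label == l] <- a_p
    counts$noncases[counts$label == l] <- length(y_sets[[l]]) - a_p
  }

  ref_cases <- counts$cases[counts$label == reference_label]
  result <- if (ref_cases > 0) {
    stratified_rr(counts, reference_label, chi2 = chi2, alpha = alpha)
  } else {
    undefined_result(counts, reference_label)
  }

  leakage <- list(
    x_size = length(x_ids),
    class_sizes = setNames(vapply(y_sets, length, integer(1)), labels),
    intersections = setNames(counts$cases, counts$label))

  structure(list(counts = counts, result = result, transcript = transcript,
                 leakage = leakage,
                 sizes = c(alice = length(x_ids),
                           bob = sum(lengths(y_sets)))),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> |X| = %d, |Y| = %d\n",
              x$sizes[["alice"]], x$sizes[["bob"]]))
  print(x$result)
  invisible(x)
}

#' Audit a protocol transcript for plaintext leakage
#'
#' Serializes every wire round and checks that no plaintext
#' quasi-identifier appears verbatim anywhere in the transcript; also
#' enumerates the aggregates each party can read off the wire (set sizes
#' per round) — the protocol's declared leakage surface.
#'
#' @param transcript Transcript list from [run_protocol()] or
#'   [psi_cardinality()].
#' @param plaintext_ids Character vector of the quasi-identifiers (or any
#'   secret strings) that must not appear.
#' @return A list of class `transcript_audit`: `ok` (logical),
#'   `violations` (data frame of round index and offending identifier)
#'   and `leakage` (data frame of round, role, layer, class, n).
#' @export
audit_transcript <- function(transcript, plaintext_ids) {
  serialized <- vapply(transcript, function(rd) {
    as.character(jsonlite::toJSON(rd[!vapply(rd, is.null, logical(1))],
                                  auto_unbox = TRUE))
  }, character(1))
  violations <- do.call(rbind, lapply(seq_along(serialized), function(i) {
    hit <- vapply(plaintext_ids,
                  function(id) grepl(id, serialized[i], fixed = TRUE),
                  logical(1))
    if (any(hit)) data.frame(round = i, id = plaintext_ids[hit]) else NULL
  }))
  leakage <- do.call(rbind, lapply(seq_along(transcript), function(i) {
    rd <- transcript[[i]]
    data.frame(round = i, role = rd$role, layer = rd$layer,
               class = rd$class %||% NA_character_, n = rd$n)
  }))
  structure(list(ok = is.null(violations),
                 violations = violations %||%
                   data.frame(round = integer(0), id = character(0)),
                 leakage = leakage),
            class = "transcript_audit")
}

#' @export
print.transcript_audit <- function(x, ...) {
  cat(sprintf("<transcript_audit> %s\n",
              if (x$ok) "clean: no plaintext identifier on the wire"
              else sprintf("FAILED: %d plaintext occurrence(s)",
                           nrow(x$violations))))
  print(x$leakage, row.names = FALSE)
  invisible(x)
}

# ---- internal ----

check_disjoint <- function(y_sets) {
  all_ids <- unlist(y_sets, use.names = FALSE)
  abort_if(anyDuplicated(all_ids) > 0,
           "exposure classes are not disjoint: %d quasi-ID(s) shared",
           sum(duplicated(all_ids)))
  invisible(TRUE)
}

undefined_result <- function(counts, reference_label) {
  out <- data.frame(label = counts$label, cases = counts$cases,
                    noncases = counts$noncases, size = counts$size,
                    rr = NA_real_, n_total = NA_real_, chi2 = NA_real_,
                    reject = NA)
  attr(out, "reference") <- reference_label
  attr(out, "undefined_rr") <- TRUE
  class(out) <- c("stratified_result", "data.frame")
  out
}
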