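# Commutative encryption and PSI cardinality.

test_that("group parameter generation satisfies all invariants", {
  gp <- generate_group_params(64, 32, seed = 7)
  expect_equal(pprisk:::.bn_num_bits(gp$p), 64)
  expect_equal(pprisk:::.bn_num_bits(gp$q), 32)
  # cofactor * q + 1 = p, exact
  p_num <- as.numeric(gp$p)
  expect_equal(as.numeric(gp$cofactor) * as.numeric(gp$q) + 1, p_num,
               tolerance = 1e-12)
  # determinism
  expect_identical(gp, generate_group_params(64, 32, seed = 7))
  expect_false(identical(gp$p, generate_group_params(64, 32, seed = 8)$p))
})

test_that("generated primes agree with an independent Miller-Rabin oracle", {
  # small enough that the double-arithmetic oracle is exact
  gp <- generate_group_params(24, 16, seed = 3)
  expect_true(oracle_is_prime(as.numeric(gp$p)))
  expect_true(oracle_is_prime(as.numeric(gp$q)))
  expect_equal((as.numeric(gp$p) - 1) %% as.numeric(gp$q), 0)
})

test_that("hand-supplied toy parameters are accepted and validated", {
  gp <- toy_group()
  expect_equal(gp$cofactor, "2")
  expect_error(group_params(24, 11), "not prime")
  expect_error(group_params(23, 7), "does not divide")
})

test_that("hash_to_group is deterministic and lands in the subgroup", {
  gp <- toy_group()
  e1 <- hash_to_group("message", gp)
  expect_identical(e1, hash_to_group("message", gp))
  # subgroup check by direct exponentiation and by enumeration
  two <- hash_to_group(c("alpha", "beta"), gp)
  expect_true(all(pprisk:::.bn_mod_exp(two, gp$q, gp$p) == "1"))
  expect_true(all(as.numeric(two) %in% toy_subgroup()))
  # larger group: e^q = 1 as well
  gp64 <- small_group()
  e <- hash_to_group(c("x", "y", "z"), gp64)
  expect_true(all(is_group_element(e, gp64)))
  expect_error(hash_to_group("", gp), "non-empty")
})

test_that("encryption commutes, inverts, and respects the identity key", {
  gp <- small_group()
  e <- hash_to_group(sprintf("m%d", 1:10), gp)
  one <- commutative_key(gp, exponent = 1)
  expect_identical(commute_encrypt(e, one, gp), e)
  for (trial in 1:5) {
    u <- commutative_key(gp, seed = 100 + trial)
    v <- commutative_key(gp, seed = 200 + trial)
    fg <- commute_encrypt(commute_encrypt(e, u, gp), v, gp)
    gf <- commute_encrypt(commute_encrypt(e, v, gp), u, gp)
    expect_identical(fg, gf)
    expect_identical(commute_decrypt(commute_encrypt(e, u, gp), u, gp), e)
  }
  expect_error(commute_encrypt("0", u, gp), "outside")
  expect_error(commute_encrypt(gp$p, u, gp), "outside")
})

test_that("key exponents stay in [1, q-1] and are seed-reproducible", {
  gp <- small_group()
  keys <- vapply(1:50, function(s) commutative_key(gp, seed = s)$exponent,
                 character(1))
  for (k in keys) {
    expect_gte(pprisk:::.bn_cmp(k, "1"), 0)
    expect_lt(pprisk:::.bn_cmp(k, gp$q), 0)
  }
  expect_identical(commutative_key(gp, seed = 5)$exponent,
                   commutative_key(gp, seed = 5)$exponent)
  expect_error(commutative_key(gp, exponent = gp$q), "outside")
})

test_that("psi_cardinality handles the degenerate and identity cases", {
  gp <- small_group()
  expect_equal(psi_cardinality(c("a", "b"), c("c", "d"), gp, 1, 2)$count, 0)
  s <- sprintf("id%d", 1:8)
  expect_equal(psi_cardinality(s, s, gp, 3, 4)$count, 8)
  r <- psi_cardinality(character(0), c("a"), gp, 1, 2)
  expect_equal(r$count, 0)
  expect_equal(r$transcript[[1]]$n, 0)
  expect_error(psi_cardinality(c("a", "a"), "b", gp, 1, 2), "duplicates")
})

test_that("psi_cardinality matches the plaintext oracle on planted overlap", {
  gp <- small_group()
  sets <- random_id_sets(100, 100, 37, seed = 11)
  r <- psi_cardinality(sets$a, sets$b, gp, 21, 22)
  expect_equal(r$count, 37)
  expect_equal(r$count, length(oracle_intersection(sets$a, sets$b)))
})

test_that("psi_cardinality equals the plaintext oracle over random pairs", {
  gp <- small_group()
  for (trial in 1:20) {
    n_a <- (trial * 13) %% 41
    n_b <- (trial * 17) %% 41
    k <- (trial * 5) %% (min(n_a, n_b) + 1)
    sets <- random_id_sets(n_a, n_b, k, seed = 3000 + trial)
    r <- psi_cardinality(sets$a, sets$b, gp, trial, 999 - trial)
    expect_equal(r$count, length(oracle_intersection(sets$a, sets$b)))
  }
})

test_that("psi_elements recovers exactly the planted intersection", {
  gp <- small_group()
  sets <- random_id_sets(30, 25, 9, seed = 77)
  r <- psi_elements(sets$a, sets$b, gp, 5, 6)
  expect_setequal(r$elements, sets$overlap)
  expect_true(all(r$elements %in% sets$a))
  expect_true(all(r$elements %in% sets$b))
  expect_equal(psi_elements(c("p", "q"), c("r"), gp, 1, 2)$elements,
               character(0))
})

test_that("distinct inputs map to distinct group elements at full size", {
  gp <- generate_group_params(512, 160, seed = 9)
  ids <- sprintf("qid-%04d", 1:200)
  e <- hash_to_group(ids, gp)
  expect_equal(anyDuplicated(e), 0)
})

test_that("transcripts never contain an input identifier verbatim", {
  gp <- small_group()
  sets <- random_id_sets(20, 20, 5, seed = 13)
  r <- psi_cardinality(sets$a, sets$b, gp, 1, 2)
  aud <- audit_transcript(r$transcript, c(sets$a, sets$b))
  expect_true(aud$ok)
})

test_that("transcript serialization round-trips through JSON lines", {
  gp <- small_group()
  r <- psi_cardinality(c("a", "b", "c"), c("b", "d"), gp, 4, 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript(r$transcript, path)
  back <- read_transcript(path)
  expect_equal(length(back), 3)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$elements, r$transcript[[i]]$elements)
    expect_identical(back[[i]]$role, r$transcript[[i]]$role)
  }
})

test_that("group parameter files round-trip bit-exactly", {
  gp <- small_group()
  path <- withr::local_tempfile(fileext = ".json")
  write_group_params(gp, path)
  expect_identical(read_group_params(path), gp)
})
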