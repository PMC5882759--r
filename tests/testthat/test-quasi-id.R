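# Canonicalization, hashing, duplicate histograms, entropy arithmetic.

test_that("canonicalize joins values with 0x1F in option order", {
  opt <- attribute_option(c("name_kana", "birthday", "address"), "E")
  rec <- list(name_kana = "yamada tarou", birthday = "1970-01-02",
              address = "tokyo nakano 4-21-1", sex = "m")
  b <- canonicalize(rec, opt)
  expect_equal(sum(b == as.raw(0x1f)), 2)
  expect_identical(b, canonicalize(rec, opt))
  # separator prevents boundary ambiguity
  o2 <- attribute_option(c("name_kana", "address"), "F")
  b1 <- canonicalize(list(name_kana = "ab", address = "c"), o2)
  b2 <- canonicalize(list(name_kana = "a", address = "bc"), o2)
  expect_false(identical(b1, b2))
  expect_error(canonicalize(list(name_kana = "x"), opt), "birthday")
})

test_that("canonicalization applies NFKC, trim, and lower-casing", {
  opt <- attribute_option("address", "X")
  expect_identical(canonicalize(list(address = "  TOKYO "), opt),
                   charToRaw("tokyo"))
  # fullwidth letters normalize to ASCII
  expect_identical(canonicalize(list(address = "ＯＳ"), opt),
                   charToRaw("os"))
})

test_that("quasi_id matches frozen independent SHA-256 digests", {
  golden <- read.csv(system.file("extdata", "golden_quasi_ids.csv",
                                 package = "pprisk"),
                     stringsAsFactors = FALSE, encoding = "UTF-8")
  for (i in seq_len(nrow(golden))) {
    opt <- standard_option(golden$option[i])
    expect_identical(quasi_id(golden[i, ], opt), golden$digest[i])
  }
})

test_that("quasi_id depends only on the attributes inside the option", {
  opt <- standard_option("E")  # no sex
  r1 <- list(name_kana = "a", birthday = "1970-01-01", address = "t",
             sex = "m")
  r2 <- modifyList(r1, list(sex = "f"))
  expect_identical(quasi_id(r1, opt), quasi_id(r2, opt))
  r3 <- modifyList(r1, list(birthday = "1970-01-02"))
  expect_false(identical(quasi_id(r1, opt), quasi_id(r3, opt)))
})

test_that("quasi_id_table agrees with per-record quasi_id", {
  df <- data.frame(name_kana = c("a", "b"), sex = c("m", "f"),
                   birthday = c("1970-01-01", "1980-02-02"),
                   address = c("x", "y"), stringsAsFactors = FALSE)
  opt <- standard_option("D")
  expect_identical(quasi_id_table(df, opt),
                   vapply(1:2, function(i) quasi_id(df[i, ], opt),
                          character(1)))
})

test_that("duplicate_histogram counts groups and conserves records", {
  opt <- attribute_option("name_kana", "X")
  all_distinct <- data.frame(name_kana = letters[1:5])
  h <- duplicate_histogram(all_distinct, opt)
  expect_equal(h$unresolved, 0)
  expect_equal(h$max_group, 1)

  h2 <- duplicate_histogram(data.frame(name_kana = c("a", "b", "b", "c")),
                            opt)
  expect_equal(h2$unresolved, 2)
  expect_equal(h2$max_group, 2)
  expect_equal(unname(h2$counts[["1"]]), 2)

  # conservation across several random fixtures
  for (s in 1:5) {
    df <- withr::with_seed(s, data.frame(
      name_kana = sample(letters[1:8], 40, replace = TRUE)))
    h3 <- duplicate_histogram(df, opt)
    expect_equal(sum(h3$counts), 40)
  }
})

test_that("generated populations reproduce the planted duplicate groups", {
  spec <- cohort_spec(population = 3000, seed = 99)
  cohort <- generate_cohort(spec)
  h <- duplicate_histogram(cohort$bob, attribute_option("name_kana", "X"))
  # generator plants floor(n * x^-s / (S * x)) groups of each size x
  n <- spec$population
  s <- spec$name_model$s
  norm <- sum((1:10000)^(-s))
  for (x in 2:h$max_group) {
    planted <- floor(n * x^(-s) / norm / x)
    got <- unname(h$counts[as.character(x)]) / x
    got <- ifelse(is.na(got), 0, got)
    expect_equal(got, planted)
  }
  expect_equal(sum(h$counts), nrow(cohort$bob))
})

test_that("empirical entropy hits its bounds and the hand-computed case", {
  expect_equal(empirical_entropy(data.frame(sex = rep("m", 10)), "sex"), 0)
  df <- data.frame(name_kana = sprintf("n%d", 1:16))
  expect_equal(empirical_entropy(df, "name_kana"), 4)  # log2(16)
  # tuple counts (2, 1, 1) -> 1.5 bit
  df2 <- data.frame(name_kana = c("a", "a", "b", "c"))
  expect_equal(empirical_entropy(df2, "name_kana"), 1.5)
  # bounds on random fixtures
  for (s in 1:5) {
    df3 <- withr::with_seed(s, data.frame(
      address = sample(letters[1:6], 30, replace = TRUE)))
    h <- empirical_entropy(df3, "address")
    expect_gte(h, 0)
    expect_lte(h, log2(30))
  }
})

test_that("entropy budgeting reproduces the sex-plus-birthday figures", {
  expect_equal(round(model_entropy_sum(c(1, log2(365))), 2), 9.51)
  expect_equal(round(attribute_entropy_preset("birthday_day"), 2), 8.51)
  expect_equal(model_entropy_sum(numeric(0)), 0)
  expect_equal(round(expected_classes(9.51)), 729)
  expect_equal(expected_classes(0), 1)
  expect_equal(expected_classes(27), 134217728)
  expect_error(model_entropy_sum(-1), "non-negative")
})
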