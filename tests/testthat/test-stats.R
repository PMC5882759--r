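# Contingency-table statistics: RR, OR, chi-squared variants, z, critical
# values, stratified tables.

men_T <- function() contingency_table(25, 7865, 79, 13915)

test_that("relative risk reproduces the published per-class values", {
  expect_equal(round(relative_risk(men_T()), 2), 0.56)
  expect_equal(round(relative_risk(contingency_table(32, 10283, 40, 14347)),
                     2), 1.12)
  # equal row risks -> RR exactly 1
  expect_equal(relative_risk(contingency_table(10, 90, 20, 180)), 1)
  expect_error(relative_risk(contingency_table(1, 1, 0, 5)), "reference")
  expect_error(relative_risk(contingency_table(0, 0, 2, 5)), "exposed")
})

test_that("odds ratio approximates RR for rare outcomes", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1)
  expect_equal(odds_ratio(contingency_table(2, 3, 5, 7)), 14 / 15)
  t <- men_T()
  expect_lt(abs(odds_ratio(t) - relative_risk(t)), 0.01)
  expect_error(odds_ratio(contingency_table(1, 0, 1, 1)), "undefined")
})

test_that("uncorrected chi-squared reproduces the published statistics", {
  expect_equal(round(chi_square_uncorrected(men_T()), 2), 6.54)
  expect_equal(round(chi_square_uncorrected(
    contingency_table(36, 8229, 79, 13915)), 2), 1.68)
  # independence: ad = bc
  expect_equal(chi_square_uncorrected(contingency_table(2, 4, 3, 6)), 0)
  expect_error(chi_square_uncorrected(contingency_table(0, 0, 3, 6)),
               "margin")
})

test_that("Yates closed form equals the four-cell sum oracle", {
  expect_equal(chi_square_yates(contingency_table(2, 4, 3, 6)), 0)
  t <- men_T()
  expect_equal(chi_square_yates(t),
               oracle_yates_cells(t$a, t$b, t$c, t$d),
               tolerance = 1e-9)
  # floor: |ad - bc| = 1 < N/2
  expect_equal(chi_square_yates(contingency_table(1, 1, 1, 2)), 0)
})

test_that("Yates closed form matches the cell sum on 1000 random tables", {
  tabs <- withr::with_seed(42, {
    matrix(sample(1:500, 4000, replace = TRUE), ncol = 4)
  })
  for (i in seq_len(nrow(tabs))) {
    tab <- contingency_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    closed <- chi_square_yates(tab)
    cells <- oracle_yates_cells(tabs[i, 1], tabs[i, 2], tabs[i, 3],
                                tabs[i, 4])
    expect_equal(closed, cells, tolerance = 1e-9)
  }
})

test_that("z statistic honours the continuity conventions", {
  # ad - bc = +N/2 with the minus correction -> 0
  t <- contingency_table(3, 1, 1, 3)  # ad - bc = 8, N/2 = 4
  expect_equal(z_statistic(t, "minus"),
               sqrt(t$N - 1) * (8 - 4) / sqrt(t$n1 * t$n2 * t$m1 * t$m2))
  t2 <- contingency_table(2, 1, 1, 2)  # ad - bc = 3 = N/2
  expect_equal(z_statistic(t2, "minus"), 0)
  # published cells: |z| beyond the two-sided 5% bound
  expect_gt(abs(z_statistic(men_T())), 1.960)
  # algebraic identity z^2 = chi2_yates * (N - 1) / N under shrink
  for (cells in list(c(25, 7865, 79, 13915), c(5, 10, 9, 4),
                     c(40, 60, 55, 45))) {
    tt <- do.call(contingency_table, as.list(cells))
    expect_equal(z_statistic(tt)^2,
                 chi_square_yates(tt) * (tt$N - 1) / tt$N,
                 tolerance = 1e-9)
  }
})

test_that("critical values come from the inverse CDFs", {
  expect_equal(round(critical_value("chi2_1df", 0.05), 2), 3.84)
  expect_equal(round(critical_value("normal_two_sided", 0.05), 3), 1.960)
  # numeric-inversion oracle at alpha = 0.5
  oracle <- uniroot(function(x) pchisq(x, 1) - 0.5, c(0, 10),
                    tol = 1e-10)$root
  expect_equal(critical_value("chi2_1df", 0.5), oracle, tolerance = 1e-6)
  expect_error(critical_value("chi2_1df", 0), "alpha")
  expect_error(critical_value("chi2_1df", 1), "alpha")
})

test_that("stratified_rr reproduces both published stratified tables", {
  men <- stratified_rr(men_counts(), "L")
  expect_equal(round(men$rr, 2), c(1.00, 0.77, 0.56, 0.57))
  expect_equal(round(men$chi2[-1], 2), c(1.68, 6.54, 7.20))
  expect_true(is.na(men$chi2[1]))
  expect_equal(men$rr[1], 1.0)
  expect_equal(men$reject[-1], c(FALSE, TRUE, TRUE))

  women <- stratified_rr(women_counts(), "L")
  expect_equal(round(women$rr, 2), c(1.00, 0.98, 1.12, 0.80))
  expect_equal(round(women$chi2[-1], 2), c(0.01, 0.21, 0.61))
  expect_false(any(women$reject[-1]))
})

test_that("stratified_rr handles the degenerate configurations", {
  one <- stratified_rr(data.frame(label = "L", cases = 3, noncases = 7), "L")
  expect_equal(nrow(one), 1)
  expect_equal(one$rr, 1.0)
  expect_error(stratified_rr(men_counts(), "Z"), "reference")
  expect_error(
    stratified_rr(data.frame(label = c("L", "S"), cases = c(0, 2),
                             noncases = c(5, 5)), "L"),
    "zero cases")
})

test_that("type-I error of the uncorrected chi-squared is near nominal", {
  # H0: both classes share risk 0.3; moderate N = 500 per class
  n1 <- 500; n2 <- 500; p0 <- 0.3; reps <- 10000
  stats <- withr::with_seed(20240901, {
    a <- rbinom(reps, n1, p0)
    c_ <- rbinom(reps, n2, p0)
    pprisk:::chi2_uncorrected_cells(a, n1 - a, c_, n2 - c_)
  })
  rate <- mean(stats > critical_value("chi2_1df", 0.05))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("RR and OR agree under rarity across random tables", {
  tabs <- withr::with_seed(8, {
    n1 <- sample(5000:20000, 50)
    n2 <- sample(5000:20000, 50)
    a <- rbinom(50, n1, 0.004) + 1  # keep cells positive
    c_ <- rbinom(50, n2, 0.004) + 1
    data.frame(a = a, b = n1 - a, c = c_, d = n2 - c_)
  })
  for (i in seq_len(nrow(tabs))) {
    t <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_lt(abs(odds_ratio(t) / relative_risk(t) - 1), 0.01)
  }
})
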