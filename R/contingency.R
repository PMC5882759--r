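# 2x2 contingency statistics in the exposure-row orientation:
#
#                cases   non-cases   total
#   exposed        a         b       n1 = a + b
#   reference      c         d       n2 = c + d
#   total        m1=a+c    m2=b+d    N
#
# RR = (a/n1) / (c/n2); chi-squared computed from the cells with integer
# cross-product arithmetic (ad - bc exact, division last).

#' Construct a 2x2 contingency table
#'
#' @param a Exposed cases.
#' @param b Exposed non-cases.
#' @param c Reference (unexposed) cases.
#' @param d Reference non-cases.
#' @return An object of class `contingency_table` with the four cells and
#'   derived margins `n1`, `n2`, `m1`, `m2` and total `N`.
#' @examples
#' contingency_table(25, 7865, 79, 13915)
#' @export
contingency_table <- function(a, b, c, d) {
  for (cell in list(a = a, b = b, c = c, d = d)) {
    abort_if(!is_count(cell), "cells must be non-negative integers")
  }
  # doubles: counts stay exact below 2^53 and cross-products cannot
  # overflow the 32-bit integer range
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  abort_if(N < 1, "table must contain at least one observation")
  structure(list(a = a, b = b, c = c, d = d,
                 n1 = a + b, n2 = c + d, m1 = a + c, m2 = b + d, N = N),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "reference"),
                              c("cases", "non-cases")))
  print(m)
  cat(sprintf("N = %.0f\n", x$N))
  invisible(x)
}

#' Relative risk of a 2x2 table
#'
#' `RR = (a / (a + b)) / (c / (c + d))`: the disease probability among
#' the exposed over that in the reference group.  Values above 1 indicate
#' elevated risk under exposure.
#'
#' @param table A [contingency_table()].
#' @return The relative risk (positive real).
#' @examples
#' relative_risk(contingency_table(25, 7865, 79, 13915))  # ~0.56
#' @export
relative_risk <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  abort_if(table$n1 == 0, "undefined RR: no exposed observations (a + b = 0)")
  abort_if(table$c == 0, "undefined RR: no cases in the reference group")
  (table$a / table$n1) / (table$c / table$n2)
}

#' Odds ratio of a 2x2 table
#'
#' `OR = ad / bc`; approximates the relative risk when the outcome is
#' rare in both rows (`a << b`, `c << d`).
#'
#' @inheritParams relative_risk
#' @return The odds ratio.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  abort_if(table$b == 0 || table$c == 0,
           "undefined OR: zero cell in denominator (b or c)")
  (table$a * table$d) / (table$b * table$c)
}

#' Chi-squared statistic, uncorrected
#'
#' `N (ad - bc)^2 / (n1 n2 m1 m2)` — the Pearson statistic with one
#' degree of freedom, zero exactly at independence (`ad = bc`).  This is
#' the variant the stratified protocol reports by default.
#'
#' @inheritParams relative_risk
#' @return Non-negative statistic, approximately chi-squared with 1 df
#'   under the null.
#' @examples
#' chi_square_uncorrected(contingency_table(25, 7865, 79, 13915))  # ~6.54
#' @export
chi_square_uncorrected <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  check_margins(table)
  chi2_uncorrected_cells(table$a, table$b, table$c, table$d)
}

#' Chi-squared statistic with continuity correction
#'
#' The Yates-corrected closed form
#' `N (max(|ad - bc| - N/2, 0))^2 / (n1 n2 m1 m2)`, equal to the four-cell
#' sum `sum_i (|O_i - E_i| - 1/2)^2 / E_i` with expectations
#' `E_i = row * col / N`.  The correction shrinks `|ad - bc|` toward zero
#' and is floored at zero so small tables cannot produce a spurious
#' positive statistic.
#'
#' @inheritParams relative_risk
#' @return Non-negative corrected statistic.
#' @export
chi_square_yates <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  check_margins(table)
  with(table, {
    shrunk <- max(abs(a * d - b * c) - N / 2, 0)
    N * shrunk^2 / (n1 * n2 * m1 * m2)
  })
}

#' Normal-deviate statistic for a 2x2 table
#'
#' `z = sqrt(N - 1) * (ad - bc -/+ N/2) / sqrt(n1 n2 m1 m2)` — the signed
#' square-root form of the corrected chi-squared, referred to N(0, 1).
#' With `correction = "shrink"` (default) the `N/2` term moves `ad - bc`
#' toward zero and is floored there, preserving the sign of the
#' association; `"plus"`/`"minus"` apply the raw signed term;
#' `"none"` omits it.  The identity
#' `z^2 = chi_square_yates * (N - 1) / N` holds under `"shrink"`.
#'
#' @inheritParams relative_risk
#' @param correction One of `"shrink"`, `"plus"`, `"minus"`, `"none"`.
#' @return Signed statistic, approximately standard normal under the null.
#' @export
z_statistic <- function(table, correction = c("shrink", "plus", "minus",
                                              "none")) {
  stopifnot(inherits(table, "contingency_table"))
  correction <- match.arg(correction)
  check_margins(table)
  abort_if(table$N < 2, "need N >= 2")
  with(table, {
    cross <- a * d - b * c
    num <- switch(correction,
                  shrink = sign(cross) * max(abs(cross) - N / 2, 0),
                  plus = cross + N / 2,
                  minus = cross - N / 2,
                  none = cross)
    sqrt(N - 1) * num / sqrt(n1 * n2 * m1 * m2)
  })
}

#' Upper-tail critical values
#'
#' Computed from the inverse distribution functions, not a lookup table:
#' chi-squared(1 df) at `alpha = 0.05` gives 3.84; the two-sided normal
#' bound at 0.05 gives 1.960.
#'
#' @param kind `"chi2_1df"`, `"normal_two_sided"`, or
#'   `"normal_one_sided"`.
#' @param alpha Significance level in (0, 1).
#' @return The critical value cutting off the upper `alpha` (or
#'   `alpha / 2`) tail.
#' @examples
#' critical_value("chi2_1df", 0.05)         # 3.841459
#' critical_value("normal_two_sided", 0.05) # 1.959964
#' @export
critical_value <- function(kind = c("chi2_1df", "normal_two_sided",
                                    "normal_one_sided"), alpha = 0.05) {
  kind <- match.arg(kind)
  abort_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
           "alpha must lie in (0, 1)")
  switch(kind,
         chi2_1df = qchisq(alpha, df = 1, lower.tail = FALSE),
         normal_two_sided = qnorm(alpha / 2, lower.tail = FALSE),
         normal_one_sided = qnorm(alpha, lower.tail = FALSE))
}

#' Stratified relative risks against a reference class
#'
#' Given per-class case/non-case counts, computes one row per exposure
#' class: `RR_p` of class `p` against the reference class (whose row is
#' pinned at RR 1.0 with no statistic) and the uncorrected chi-squared
#' `chi2_p = N_p (a_p d - b_p c)^2 / ((a_p + b_p)(c + d)(a_p + c)(b_p + d))`
#' of the 2x2 table formed by class `p` and the reference.
#'
#' @param class_counts Data frame with columns `label`, `cases`,
#'   `noncases` (one row per exposure class), or a list of
#'   `(label, a_p, b_p)` triples.
#' @param reference_label Label of the reference class (e.g. `"L"`, the
#'   lowest-activity quartile).
#' @param chi2 `"uncorrected"` (default, the variant whose values match
#'   published stratified tables) or `"yates"`.
#' @param alpha Significance level for the per-row rejection flag.
#' @return A data frame of class `stratified_result` with columns
#'   `label`, `cases`, `noncases`, `size`, `rr`, `n_total`, `chi2`,
#'   `reject`; the reference row carries `NA` statistics and `rr = 1`.
#' @examples
#' men <- data.frame(label = c("L", "S", "T", "H"),
#'                   cases = c(79, 36, 25, 32),
#'                   noncases = c(13915, 8229, 7865, 9830))
#' stratified_rr(men, "L")
#' @export
stratified_rr <- function(class_counts, reference_label,
                          chi2 = c("uncorrected", "yates"), alpha = 0.05) {
  chi2 <- match.arg(chi2)
  cc <- normalize_class_counts(class_counts)
  abort_if(!reference_label %in% cc$label,
           "reference label '%s' not among classes", reference_label)
  ref <- cc[cc$label == reference_label, ]
  abort_if(ref$cases == 0, "reference class has zero cases: RR undefined")
  crit <- critical_value("chi2_1df", alpha)
  chi2_fun <- if (chi2 == "uncorrected") chi_square_uncorrected
              else chi_square_yates
  rows <- lapply(seq_len(nrow(cc)), function(i) {
    a <- cc$cases[i]; b <- cc$noncases[i]
    if (cc$label[i] == reference_label) {
      data.frame(label = cc$label[i], cases = a, noncases = b,
                 size = a + b, rr = 1.0, n_total = a + b,
                 chi2 = NA_real_, reject = NA)
    } else {
      tab <- contingency_table(a, b, ref$cases, ref$noncases)
      stat <- chi2_fun(tab)
      data.frame(label = cc$label[i], cases = a, noncases = b,
                 size = a + b, rr = relative_risk(tab), n_total = tab$N,
                 chi2 = stat, reject = stat > crit)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference_label
  attr(out, "chi2_variant") <- chi2
  attr(out, "alpha") <- alpha
  class(out) <- c("stratified_result", "data.frame")
  out
}

#' @export
print.stratified_result <- function(x, digits = 2, ...) {
  cat(sprintf("Stratified relative risk (reference: %s, chi2: %s)\n",
              attr(x, "reference"), attr(x, "chi2_variant")))
  show <- data.frame(class = x$label, cases = x$cases,
                     noncases = x$noncases, size = x$size,
                     RR = sprintf(paste0("%.", digits, "f"), x$rr),
                     chi2 = ifelse(is.na(x$chi2), "Reference",
                                   sprintf(paste0("%.", digits, "f"),
                                           x$chi2)))
  print(show, row.names = FALSE)
  invisible(x)
}

# ---- internal ----

check_margins <- function(table) {
  with(table, abort_if(n1 == 0 || n2 == 0 || m1 == 0 || m2 == 0,
                       "undefined statistic: zero margin"))
}

# vectorized kernel shared with simulation code
chi2_uncorrected_cells <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

normalize_class_counts <- function(class_counts) {
  if (is.data.frame(class_counts)) {
    abort_if(!all(c("label", "cases", "noncases") %in% names(class_counts)),
             "class_counts needs columns label, cases, noncases")
    cc <- class_counts[, c("label", "cases", "noncases")]
  } else {
    cc <- do.call(rbind, lapply(class_counts, function(x) {
      data.frame(label = x[[1]], cases = as.numeric(x[[2]]),
                 noncases = as.numeric(x[[3]]))
    }))
  }
  abort_if(anyDuplicated(cc$label) > 0, "duplicate class labels")
  abort_if(any(cc$cases < 0) || any(cc$noncases < 0),
           "counts must be non-negative")
  cc$label <- as.character(cc$label)
  cc
}
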