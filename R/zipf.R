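# Zipf-law model of name-frequency duplication: f(x) = a / x^s is the
# number of people belonging to duplicate-name groups of size x.  Used to
# extrapolate how (un)informative a name attribute is for identification —
# e.g. with national population D and exponent s ~ 3.87, the rank-1 count
# a = D / sum_k k^-s estimates how many people share a non-unique name.

#' Construct a Zipf duplication model
#'
#' @param a Scale: expected individuals at rank 1 (unique tuples);
#'   positive.
#' @param s Exponent; must exceed 1 so the normalizing sum
#'   `sum_k k^-s` converges.
#' @return An object of class `zipf_model`.
#' @examples
#' zipf_model(a = 110000, s = 3.87)
#' @export
zipf_model <- function(a, s) {
  abort_if(!is.numeric(a) || a <= 0, "a must be positive")
  abort_if(!is.numeric(s) || s <= 1, "s must exceed 1 for a convergent model")
  structure(list(a = a, s = s), class = "zipf_model")
}

#' @export
print.zipf_model <- function(x, ...) {
  cat(sprintf("<zipf_model> f(x) = %.6g / x^%.4g\n", x$a, x$s))
  invisible(x)
}

#' Expected individuals at duplication rank x
#'
#' `f(x) = a / x^s`, monotone decreasing in `x`.
#'
#' @param x Integer rank(s), `x >= 1`.
#' @param model A [zipf_model()].
#' @return Expected number of individuals in groups of exactly `x`
#'   identical values.
#' @export
zipf_count <- function(x, model) {
  stopifnot(inherits(model, "zipf_model"))
  abort_if(any(x < 1 | x != floor(x)), "ranks must be integers >= 1")
  model$a / x^model$s
}

# normalizing sum S(s, k_max) = sum_{k=1}^{k_max} k^-s; k_max = Inf
# truncates once an increment falls below 1e-12 of the partial sum.
zipf_norm_sum <- function(s, k_max = Inf) {
  abort_if(is.infinite(k_max) && s <= 1, "sum diverges for s <= 1")
  if (is.finite(k_max)) return(sum(seq_len(k_max)^(-s)))
  total <- 0
  k <- 1
  repeat {
    block <- sum((k:(k + 4095))^(-s))
    total <- total + block
    if (block < 1e-12 * total) break
    k <- k + 4096
    abort_if(k > 1e9, "normalizing sum failed to converge")
  }
  total
}

#' Total population implied by a Zipf model
#'
#' `D = a * sum_{k=1}^{k_max} k^-s` — summing the expected individuals
#' over every duplication rank.
#'
#' @param model A [zipf_model()].
#' @param k_max Upper rank; `Inf` (default) truncates automatically when
#'   increments become negligible (relative 1e-12).
#' @return The implied population `D`.
#' @examples
#' zipf_total_population(zipf_model(1, 3.87))  # the normalizing sum, ~1.09
#' @export
zipf_total_population <- function(model, k_max = Inf) {
  stopifnot(inherits(model, "zipf_model"))
  model$a * zipf_norm_sum(model$s, k_max)
}

#' Zipf scale from a known total population
#'
#' Inverts the population sum: `a = D / sum_k k^-s`.  With
#' `rounding = "2sf"` the normalizing sum is first rounded to two
#' significant figures (the convention used in desk estimates, where
#' `sum_k k^-3.87 ~ 1.1` turns a 120-million population into a 109-million
#' rank-1 count).
#'
#' @param D Total population; positive.
#' @param s Zipf exponent, `> 1`.
#' @param rounding `"none"` (default) or `"2sf"`.
#' @param k_max Upper rank for the normalizing sum.
#' @return The scale `a`.
#' @examples
#' zipf_constant_from_population(120e6, 3.87, rounding = "2sf")  # ~109e6
#' @export
zipf_constant_from_population <- function(D, s, rounding = c("none", "2sf"),
                                          k_max = Inf) {
  abort_if(D <= 0, "population must be positive")
  rounding <- match.arg(rounding)
  nsum <- zipf_norm_sum(s, k_max)
  if (rounding == "2sf") nsum <- signif(nsum, 2)
  D / nsum
}

#' Fit a Zipf model to a duplicate histogram
#'
#' Least squares on `(log x, log f(x))` over the ranks with nonzero
#' counts: the slope estimates `-s` and the intercept `log a`.  This is
#' the linear fit suggested by the straight-line appearance of
#' rank-frequency data on log-log axes.
#'
#' @param histogram A [duplicate_histogram()], or a named numeric vector
#'   mapping rank `x` to individuals at that rank.
#' @return A [zipf_model()].  A fitted exponent `s <= 1` (including the
#'   near-uniform `s ~ 0` case) triggers a warning, since the resulting
#'   model has no convergent population sum; the raw estimates are still
#'   returned, wrapped in an unclassed list.
#' @export
fit_zipf <- function(histogram) {
  counts <- if (inherits(histogram, "duplicate_histogram")) histogram$counts
            else histogram
  abort_if(is.null(names(counts)), "histogram must map rank -> count")
  x <- as.numeric(names(counts))
  f <- as.numeric(counts)
  keep <- f > 0
  abort_if(sum(keep) < 2, "need at least 2 nonzero ranks to fit")
  fit <- lm(log(f[keep]) ~ log(x[keep]))
  s <- -unname(coef(fit)[2])
  a <- exp(unname(coef(fit)[1]))
  if (!is.finite(s) || s <= 1) {
    warning(sprintf(
      "fitted exponent s = %.3g is not > 1: data look non-Zipf", s))
    return(list(a = a, s = s))
  }
  zipf_model(a, s)
}
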