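# Standardized mortality ratio: observed deaths O against the expectation
# E = sum_j q_j n_j accumulated over age strata, tested exactly against
# Poisson(E) or via the continuity-corrected normal deviate
# Z = (|O - E| - 0.5) / sqrt(E).

#' Assemble SMR strata
#'
#' @param deaths Integer vector `d_j`: observed deaths per age stratum.
#' @param rates Numeric vector `q_j` in `[0, 1]`: reference death rate per
#'   stratum.
#' @param population Numeric vector `n_j >= 0`: population at risk per
#'   stratum.
#' @param age_group Optional labels.
#' @return A data frame of class `smr_strata`.
#' @export
smr_strata <- function(deaths, rates, population, age_group = NULL) {
  abort_if(length(deaths) == 0, "need at least one stratum")
  abort_if(length(rates) != length(deaths) ||
           length(population) != length(deaths),
           "deaths, rates and population must have equal length")
  abort_if(any(deaths < 0 | deaths != floor(deaths)),
           "deaths must be non-negative integers")
  abort_if(any(rates < 0 | rates > 1), "rates must lie in [0, 1]")
  abort_if(any(population < 0), "population must be non-negative")
  out <- data.frame(
    age_group = age_group %||% paste0("stratum_", seq_along(deaths)),
    deaths = deaths, rate = rates, population = population)
  class(out) <- c("smr_strata", "data.frame")
  out
}

#' Expected deaths from reference rates
#'
#' `E = sum_j q_j n_j`: each stratum contributes its reference death rate
#' times its population at risk.
#'
#' @param strata An [smr_strata()] data frame (columns `rate`,
#'   `population`).
#' @return Non-negative expected count `E`.
#' @export
expected_deaths <- function(strata) {
  abort_if(nrow(strata) == 0, "strata must be non-empty")
  sum(strata$rate * strata$population)
}

#' Standardized mortality ratio
#'
#' `SMR = O / E` with `O = sum_j d_j` observed and `E` expected deaths.
#' An SMR of 1 means mortality matches the reference population.
#'
#' @param O Observed deaths (or an [smr_strata()] data frame, in which
#'   case `O` and `E` are both derived from it).
#' @param E Expected deaths; must be positive.
#' @return The ratio `O / E`.
#' @export
smr <- function(O, E = NULL) {
  if (inherits(O, "smr_strata")) {
    E <- expected_deaths(O)
    O <- sum(O$deaths)
  }
  abort_if(is.null(E) || E <= 0, "undefined SMR: E must be positive")
  O / E
}

#' Exact Poisson upper-tail p-value
#'
#' `p = P(X >= O) = 1 - sum_{j=0}^{O-1} E^j e^{-E} / j!` for
#' `X ~ Poisson(E)`: the one-sided probability of observing at least `O`
#' deaths when `E` are expected.  Evaluated through the Poisson CDF
#' (log-space internally), so large `E` does not overflow.  Equals 1 at
#' `O = 0` and is monotone non-increasing in `O`.
#'
#' @param O Observed count, non-negative integer (vectorized).
#' @param E Expected count, positive.
#' @return p-value in `[0, 1]`.
#' @examples
#' poisson_tail_p(3, 1)  # 1 - e^-1 (1 + 1 + 1/2) = 0.0803
#' @export
poisson_tail_p <- function(O, E) {
  abort_if(any(O < 0 | O != floor(O)), "O must be a non-negative integer")
  abort_if(E <= 0, "E must be positive")
  ppois(O - 1, lambda = E, lower.tail = FALSE)
}

#' Normal-approximation SMR test
#'
#' Continuity-corrected deviate for the SMR: two-sided
#' `Z = (|O - E| - 0.5) / sqrt(E)` compared against the upper
#' `alpha / 2` normal quantile; one-sided `Z = (O - E - 0.5) / sqrt(E)`
#' (the half-unit correction always shrinking the discrepancy) against
#' the upper `alpha` quantile.  The approximation is conventionally
#' trusted for `E >= 5`; below that a warning is attached and the exact
#' [poisson_tail_p()] should be preferred.
#'
#' @param O Observed deaths.
#' @param E Expected deaths, positive.
#' @param sided `"two"` (default) or `"one"` (upper tail).
#' @param alpha Significance level.
#' @return A list of class `test_result`: `statistic`, `kind = "z"`,
#'   `alpha`, `critical`, `reject`, `p` (normal tail), and
#'   `p_exact` (the Poisson tail, one-sided).
#' @export
smr_z <- function(O, E, sided = c("two", "one"), alpha = 0.05) {
  sided <- match.arg(sided)
  abort_if(E <= 0, "E must be positive")
  if (E < 5) {
    warning("normal approximation is unreliable for E < 5; ",
            "use poisson_tail_p")
  }
  z <- if (sided == "two") (abs(O - E) - 0.5) / sqrt(E)
       else (O - E - 0.5) / sqrt(E)
  crit <- critical_value(
    if (sided == "two") "normal_two_sided" else "normal_one_sided", alpha)
  p <- if (sided == "two") 2 * pnorm(abs(O - E) - 0.5, sd = sqrt(E),
                                     lower.tail = FALSE)
       else pnorm(z, lower.tail = FALSE)
  structure(list(statistic = z, kind = "z", alpha = alpha, critical = crit,
                 reject = z > crit, p = min(p, 1),
                 p_exact = poisson_tail_p(round(O), E),
                 smr = smr(O, E)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s = %.4f, critical = %.4f (alpha = %g): %s\n",
              x$kind, x$statistic, x$critical, x$alpha,
              if (isTRUE(x$reject)) "reject H0" else "do not reject H0"))
  if (!is.null(x$p)) cat(sprintf("  p = %.4g", x$p))
  if (!is.null(x$p_exact)) cat(sprintf(" (exact Poisson p = %.4g)",
                                       x$p_exact))
  cat("\n")
  invisible(x)
}
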