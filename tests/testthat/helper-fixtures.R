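# Shared fixtures and independent oracles.  Oracles are deliberately
# naive re-implementations (enumeration, term-by-term summation, direct
# simulation) kept separate from the code paths they check.

# hand-checkable toy group: 11 | 22
toy_group <- function() group_params(23, 11)

# small fast group for property tests (cached per session)
small_group <- local({
  gp <- NULL
  function() {
    if (is.null(gp)) gp <<- generate_group_params(64, 32, seed = 2024)
    gp
  }
})

men_counts <- function() colon_activity_counts("men")
women_counts <- function() colon_activity_counts("women")

option_d <- function() standard_option("D")

# enumeration of the order-11 subgroup of Z_23^*: powers of 2 (2^11 = 1
# mod 23, so 2 generates the subgroup)
toy_subgroup <- function() {
  e <- 1
  out <- integer(0)
  repeat {
    e <- (e * 2) %% 23
    out <- c(out, e)
    if (e == 1) break
  }
  sort(out)
}

# plaintext set-intersection oracle
oracle_intersection <- function(a, b) sort(intersect(a, b))

# plaintext join oracle: per-class case / non-case counts from raw tables
oracle_class_counts <- function(alice, bob, option) {
  x <- unique(quasi_id_table(alice, option))
  labels <- unique(bob$exposure_class)
  do.call(rbind, lapply(labels, function(l) {
    y <- unique(quasi_id_table(bob[bob$exposure_class == l, , drop = FALSE],
                               option))
    data.frame(label = l, cases = length(intersect(x, y)),
               noncases = length(setdiff(y, x)))
  }))
}

# four-cell-sum Yates oracle: sum_i (|O_i - E_i| - 1/2)^2 / E_i with the
# per-cell correction floored at zero
oracle_yates_cells <- function(a, b, c, d) {
  N <- a + b + c + d
  O <- c(a, b, c, d)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / N
  sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
}

# term-by-term Poisson upper tail: 1 - sum_{j<O} E^j e^-E / j!
oracle_poisson_tail <- function(O, E) {
  if (O == 0) return(1)
  j <- 0:(O - 1)
  1 - sum(exp(j * log(E) - E - lgamma(j + 1)))
}

# naive Miller-Rabin on doubles; exact for n < 2^26 (products < 2^52)
oracle_is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n %% 2 == 0) return(n == 2)
  for (p in c(3, 5, 7, 11, 13)) {
    if (n == p) return(TRUE)
    if (n %% p == 0) return(FALSE)
  }
  d <- n - 1
  r <- 0
  while (d %% 2 == 0) {
    d <- d / 2
    r <- r + 1
  }
  powmod <- function(b, e, m) {
    acc <- 1
    b <- b %% m
    while (e > 0) {
      if (e %% 2 == 1) acc <- (acc * b) %% m
      b <- (b * b) %% m
      e <- e %/% 2
    }
    acc
  }
  for (a in c(2, 3, 5, 7, 11, 13, 17)) {
    x <- powmod(a, d, n)
    if (x == 1 || x == n - 1) next
    ok <- FALSE
    for (i in seq_len(r - 1)) {
      x <- (x * x) %% n
      if (x == n - 1) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

random_id_sets <- function(n_a, n_b, n_overlap, seed) {
  withr::with_seed(seed, {
    n_pool <- n_a + n_b - n_overlap
    pool <- paste0(vapply(seq_len(n_pool), function(i) {
      paste(sample(letters, 8, replace = TRUE), collapse = "")
    }, character(1)), "-", seq_len(n_pool))  # suffix guarantees uniqueness
    shared <- pool[seq_len(n_overlap)]
    only_a <- pool[n_overlap + seq_len(n_a - n_overlap)]
    only_b <- pool[n_a + seq_len(n_b - n_overlap)]
    list(a = sample(c(shared, only_a)), b = sample(c(shared, only_b)),
         overlap = shared)
  })
}
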