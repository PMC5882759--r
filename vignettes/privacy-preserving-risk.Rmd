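---
title: "Privacy-preserving stratified relative risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving stratified relative risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprisk)
```

## The problem

Two institutions hold complementary halves of an epidemiological question.
A case registry (call its keeper Alice) knows *who* has the disease — for
instance a national cancer registry's colon-cancer cases.  A survey
provider (Bob) knows an *exposure* for a partially overlapping population —
for instance daily physical activity summarized as METs quartiles
(`L`owest, `S`econd, `T`hird, `H`ighest).  Estimating how exposure
modulates disease risk requires linking the two tables person by person,
but neither party may reveal its roster: cancer status and survey answers
are both confidential, and the two tables share no common identifier.

`pprisk` implements the full pipeline that solves this:

1. **Record linkage without identifiers** — each party reduces a record to
   a *quasi-identifier*: a SHA-256 digest of a canonicalized combination of
   personal attributes (name, sex, birthday, address).
2. **Private set intersection cardinality (PSI-CA)** — the parties learn
   the *sizes* of the per-class intersections, and nothing else, through a
   commutative-encryption protocol.
3. **Stratified inference** — the intersection counts populate 2×2
   contingency tables per exposure class, yielding relative risks and
   chi-squared statistics; a standardized-mortality-ratio (SMR) Poisson
   test covers the rate-comparison variant of the question.
4. **Identifiability accounting** — entropy and Zipf-law models quantify
   whether a chosen attribute combination actually individuates people.

## The cryptographic core

### Commutative encryption

Work in the order-$q$ subgroup of $\mathbb{Z}_p^*$, with $p$, $q$ prime and
$q \mid p - 1$.  Each party holds a secret exponent ($u$ for Alice, $v$
for Bob) drawn uniformly from $[1, q-1]$, and "encryption" is

$$f(m) = H(m)^u \bmod p, \qquad g(m) = H(m)^v \bmod p,$$

where $H$ hashes a message onto the subgroup.  Because exponentiation
commutes, $f(g(m)) = g(f(m))$: if both parties apply their secret layer to
the same message the results collide, regardless of order.  Equal inputs
are therefore recognizable *after double encryption* while single-encrypted
values are indistinguishable from random subgroup elements under the
decisional Diffie–Hellman assumption.

The protocol per class:

1. Alice sends $\{H(x)^u : x \in X\}$, shuffled.
2. Bob returns $\{H(x)^{uv}\}$, re-shuffled, plus $\{H(y)^v : y \in Y_p\}$.
3. Alice computes $\{H(y)^{vu}\}$ locally and counts collisions between
   the two double-encrypted sets: $a_p = |X \cap Y_p|$.

Only blinded group elements and set sizes ever cross the wire.  An
element-revealing variant keeps the pairs $(H(x)^u, H(x)^{uv})$ aligned in
round 2 so the initiator can map collisions back to her own inputs.

### Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| modulus bits $|p|$ | 2048 | standard discrete-log hardness margin |
| subgroup bits $|q|$ | 160 | exponent cost scales with $|q|$, not $|p|$; matches the classic Schnorr-group sizing |
| hash | SHA-256 | collision resistance for 32-byte quasi-IDs |
| Miller–Rabin rounds | OpenSSL `BN_check_prime` (error < $2^{-128}$) | probabilistic testing suffices for an artifact; primality proofs buy nothing here |
| toy-group floor | 16-bit | lets property tests run thousands of protocol rounds in seconds |

Parameter generation is *deterministic given a seed*: candidates come from
a SHA-256 counter stream, never from an ambient RNG, so a
(`p_bits`, `q_bits`, `seed`) triple names one reproducible group.

### Numerical/cryptographic choices worth recording

* **Hash-to-group** is the SHA-256 digest of `message || counter`
  (counter 4-byte big-endian from 0) reduced mod $p$ and raised to the
  cofactor $(p-1)/q$.  Cofactor exponentiation guarantees subgroup
  membership without fixing a generator; the counter retries on the rare
  identity outcome (and makes toy groups usable, where identity hits are
  common).
* **Shuffling**: the source material is silent on whether exchanged lists
  are permuted, but unshuffled lists would leak input order, so every
  outgoing list passes through a seeded Fisher–Yates shuffle.  This is
  mandatory, not optional.
* **Matching is set-semantics** on the double-encrypted values, so
  positions carry no information even within a round.
* **One key pair per run** across the $q$ per-class sessions, matching the
  single-protocol framing of the stratified computation; permutations are
  fresh per message.  Class sizes $|Y_p|$ travel in clear — they are needed
  to form $b_p = |Y_p| - a_p$ — and the transcript audit lists them
  explicitly as part of the declared leakage surface
  $\{|X|, |Y_p|, a_p\}$.
* **Decryption** (inverse exponent mod $q$) is exposed for completeness
  and round-trip testing, although the intersection flow never needs it.

The threat model is honest-but-curious: parties follow the protocol but
mine the transcript.  Malicious behaviour (wrong inputs, malformed
elements) is *not* defended against, and the arithmetic is not
constant-time; see Limitations.

## Quasi-identifiers

A quasi-identifier is `SHA-256(canonical(attributes))` where
canonicalization applies Unicode NFKC, trims, lower-cases, and joins the
selected attribute values with the `0x1F` unit separator.  The separator
choice makes the encoding injective for separator-free values — plain
string concatenation would confuse `("ab", "c")` with `("a", "bc")`.
NFKC also folds full-width/half-width variants, the main source of
spurious mismatch in Japanese administrative text; deeper orthographic
unification (kana/kanji transliteration) is out of scope.

Whether a combination individuates people is an empirical question the
package answers three ways:

* `empirical_entropy()` — Shannon entropy $-\sum_k P(k)\log_2 P(k)$ of the
  observed attribute tuples (base 2; the non-negative convention).
* `model_entropy_sum()` / `expected_classes()` — the independence budget:
  sex (1 bit) + birthday ($\log_2 365 = 8.51$ bits) = 9.51 bits
  $\Rightarrow 2^{9.51} \approx 729$ distinguishable classes.  Two birthday
  conventions are exposed as presets: the 365-day uniform model and the
  15-bit day-plus-year convention.
* `duplicate_histogram()` / `fit_zipf()` — how many records share a tuple.
  Name-frequency data are well described by a Zipf law $f(x) = a/x^s$
  (individuals in duplicate groups of size $x$); the fit is least squares
  on $(\log x, \log f)$ over nonzero ranks, the method suggested by the
  straight-line appearance of such data on log–log axes.  With a national
  population $D = 120$ million and $s = 3.87$, inverting
  $D = a\sum_k k^{-s}$ (normalizing sum $\approx 1.09$, rounded to 1.1 in
  desk arithmetic) gives $a \approx 109$ million people with non-unique
  kana names — name alone is a poor identifier, which is why the default
  attribute option `D` adds sex, birthday and address.

## The statistics

All 2×2 tables use the exposure-row orientation

$$RR = \frac{a/(a+b)}{c/(c+d)}, \qquad
\chi^2 = \frac{N(ad-bc)^2}{n_1 n_2 m_1 m_2},$$

with $a$ = exposed cases, $c$ = reference-class cases.  Two conventions
deserve a note:

* **Which chi-squared.**  The continuity-corrected (Yates) form
  $N(|ad-bc| - N/2)^2 / (n_1 n_2 m_1 m_2)$ is available
  (`chi_square_yates`), with the correction floored at zero so sparse
  tables cannot generate spurious signal.  The *uncorrected* statistic is
  the default reported by `stratified_rr()` because it is the variant
  whose values match the published stratified tables this package
  reproduces (the men's third-quartile cells give $\chi^2 = 6.54$
  uncorrected).  The signed normal deviate
  $z = \sqrt{N-1}\,(ad-bc \mp N/2)/\sqrt{n_1 n_2 m_1 m_2}$ is provided
  with selectable correction handling; under the default shrink-toward-zero
  convention $z^2 = \chi^2_{\text{Yates}}(N-1)/N$ exactly.
* **Critical values** come from the inverse CDFs (`qchisq`, `qnorm`),
  never lookup tables: $\chi^2_1(0.05) = 3.84$, $z_{0.025} = 1.960$.

The SMR branch tests observed deaths $O$ against expectation
$E = \sum_j q_j n_j$ accumulated over age strata: exactly via the Poisson
upper tail $P(X \ge O)$ (computed through the CDF in log space — the
printed form $1 - \sum_{j<O} E^j e^{-E}/j!$ cancels catastrophically in
the far tail), or approximately via $Z = (|O-E| - 0.5)/\sqrt{E}$, which is
reliable for $E \ge 5$ (a warning is attached below that) and tracks the
exact tail within 0.02 for $E \ge 20$.

Counts are held as doubles (exact integers up to $2^{53}$), cross-products
$ad - bc$ are formed before any division, and cells are validated as
non-negative integers on construction.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the target application: a
population partitioned into $q$ exposure classes (default the four METs
quartiles with membership probabilities 0.35/0.2/0.2/0.25, a survey-like
skew toward the reference class), class-specific disease probabilities
(default 0.005/0.004/0.003/0.003 — a rare outcome whose risk declines
with activity, true RRs 1.0/0.8/0.6/0.6), duplicate names planted to
follow a Zipf model ($s = 3.87$), uniform birthdays over a 30-year span,
and a finite address pool.  A `survey_fraction` below 1 makes Bob's table
a strict subset of the population, driving the registry/survey overlap.
Ground truth (exact per-class case counts among surveyed individuals) is
recorded at generation time.

`generate_from_counts()` is the inverse: given per-class $(a_p, b_p)$
cells it constructs a cohort with collision-free attribute tuples that
realizes those cells exactly, so published contingency tables can be
replayed through the full encrypted path and must reproduce bit-for-bit.

What the generator does **not** emulate — and hence what a green test does
not establish: real name corpora (names are synthetic tokens, only their
duplication *structure* is realistic), METs questionnaire scoring (class
membership is primitive; no MET-hour thresholds are modelled), age
structure and competing risks, attribute noise or typos (linkage in the
generator is exact by construction; real-world canonicalization failures
are out of scope).

A statistical note on validating the generator: with 40,000 people and
per-mille disease risks a class holds only 30–50 expected cases, so a
realized RR has a delta-method standard error of roughly 0.10–0.15.  The
generator tests therefore check realized RRs against a 3-SE binomial
envelope computed from the planted parameters rather than a fixed ±0.15
band, which a fair seed would fail about a third of the time.

## Degenerate inputs and tie-breaks

* Empty case registry: the protocol completes, all $a_p = 0$, and every
  RR is flagged undefined rather than fabricated.
* Reference class with zero linked cases: RR is undefined; the stratified
  result carries `NA` statistics and an `undefined_rr` attribute.
* Zero margins: chi-squared and z statistics raise a named error rather
  than returning `NaN`.
* Non-disjoint exposure classes (one quasi-ID in two classes) are rejected
  before any encryption happens.
* Zipf fits with a non-convergent exponent ($s \le 1$, e.g. uniform
  counts) warn and return the raw estimates unclassed, since such a model
  has no finite population sum.
* The normalizing sum $\sum k^{-s}$ truncates when an increment falls
  below $10^{-12}$ of the partial sum.

## Limitations

* Security holds in the semi-honest model only; no defence against
  malicious inputs, and no formal proof is claimed here — the transcript
  *audit* (no plaintext identifier appears on the wire; leakage surface
  enumerated) is a test, not a proof.
* Modular exponentiation via OpenSSL BIGNUM is not constant-time; timing
  side channels are out of scope.
* Quasi-identifier linkage inherits all the failure modes of the chosen
  attribute option: people sharing every selected attribute merge, and
  records with typos fail to link.  The identifiability tools quantify the
  former; nothing here mitigates the latter.
* Relative-risk confidence intervals are not provided (only the
  chi-squared tests); hazard-ratio modelling is out of scope.
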