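Package: pprisk
Title: Privacy-Preserving Relative-Risk Estimation via Private Set
    Intersection
Version: 0.1.0
Authors@R:
    person("pprisk", "Maintainers", email = "pprisk@example.org",
           role = c("aut", "cre"))
Description: Two-party privacy-preserving hypothesis testing for cohort
    studies.  A case registry (Alice) and an exposure survey (Bob) jointly
    estimate stratified relative risks and chi-squared statistics without
    exchanging plaintext identifiers: records are canonicalized into hashed
    quasi-identifiers and linked through a private set intersection
    cardinality protocol built on a commutative Pohlig-Hellman cipher in a
    prime-order subgroup.  Also provides standardized mortality ratio
    Poisson tests, Shannon-entropy and Zipf-law models of quasi-identifier
    identifiability, a synthetic cohort generator with known ground truth,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stringi,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenSSL (libcrypto)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
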