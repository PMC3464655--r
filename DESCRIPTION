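Package: rnascfg
Title: Stochastic Context-Free Grammars for RNA Secondary Structure
    Prediction and Grammar Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for RNA secondary structure prediction with lightweight
    stochastic context-free grammars (SCFGs) restricted to a double emission
    normal form (rules T -> U V, T -> ., T -> ( U )). Provides CYK and
    inside-outside dynamic programming, gamma-weighted maximum expected
    accuracy (posterior) decoding, supervised and expectation-maximisation
    parameter training, heuristic grammar ambiguity and completeness
    diagnostics, structure comparison metrics (sensitivity, PPV, F-score,
    mountain metric), dataset filtering utilities for dot-bracket records,
    a synthetic data sampler, and search over grammar space: an evolutionary
    algorithm with five mutation operators and a breeding rule, brute-force
    enumeration of two-non-terminal grammars, and local add/delete search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
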