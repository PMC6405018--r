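Package: permexact
Title: Exact Permutation and Transformation Tests with Random Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact and level-alpha tests based on groups of data
    transformations (index permutations, sign flips, planar rotations),
    including variants that use only a random sample of transformations.
    Implements the full-group permutation test, its randomized (Hoeffding)
    adaptation, random-transformation tests with the identity adjoined,
    representative sampling over equivalence classes of the statistic,
    the subset-shift scheme for finite subsets of possibly infinite
    groups, and the associated p-value constructions ((B+1)/(w+1), the
    randomized p-value and its upper bound).  A Monte Carlo harness turns
    every level and exactness claim into a simulation experiment,
    including demonstrations of why the naive estimated p-value B/w and
    non-group transformation sets (balanced permutations) are
    anti-conservative.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
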