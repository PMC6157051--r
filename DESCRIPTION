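Package: vcselect
Title: Budget-Constrained Selection of Variant-Call Verification Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing verification studies of multi-caller
    variant-call sets under a fixed budget. Implements six candidate-selection
    strategies (uniform random rows, directed sampling over a call
    overlap-by-caller matrix, equal per caller, and equal, increasing or
    decreasing allocation across call-overlap levels), all sampling without
    replacement with largest-remainder budget apportionment and iterative
    shortfall redistribution. Estimates per-caller precision, recall and F1
    from the verified subset, in a default and an overlap-weighted precision
    mode, and compares them to full-prediction-set scores. Includes a
    synthetic multi-caller ensemble generator with known ground truth and a
    sweep harness that benchmarks strategies across budgets, caller subsets
    and replicates, ranking them by the median subset-versus-full F1
    difference.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
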