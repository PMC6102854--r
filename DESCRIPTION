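Package: screenorm
Title: Control-Anchored Normalization for Multi-Cell-Line Genetic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization and hit analysis for siRNA and CRISPR screen data
    collected across multiple cell lines. Readouts are standardized against
    negative and positive assay controls into lethality scores (0 = normal
    viability, 1 = as lethal as positive controls), optionally per plate to
    remove plate effects. A core set of score values is selected per replicate
    and a piecewise-linear, core-restricted quantile normalization aligns the
    bulk of the score distributions across replicates while preserving
    differences in their tails, where true hits live. Includes comparator
    normalizations (robust z-scores, median-centering, classic quantile
    normalization), per-feature regression tests with false discovery rate
    control, concordance metrics between hit lists, and a synthetic-screen
    generator with a false-discovery/power evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
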