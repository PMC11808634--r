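Package: hybridsize
Title: Size and Variation Analysis for Admixed Primate Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of body size in admixed
    (hybrid-zone) primate colonies with pedigree-derived ancestry fractions.
    Implements sex adjustment by group-wise male-female mean offsets,
    ancestry-weighted additive (mid-parent) expected values with parity-line
    and transgression analysis, small-sample-corrected coefficients of
    variation (V*) with a one-tailed CV-difference test, and a
    Bonferroni-corrected one-tailed t-test battery comparing hybrids to
    parental references. A seeded explicit-locus polygenic simulator with
    optional dominance (heterosis/dysgenesis) and lineage-specific sexual
    dimorphism makes every stage testable, and supports power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
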