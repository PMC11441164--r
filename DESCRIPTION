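Package: petalshift
Title: Multiscale Analysis of a Shared Blue-Orange Flower Color Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether a flower color polymorphism shared by two
    closely related species arose by convergence, introgression, ancestral
    polymorphism, or species non-monophyly. Implements distance-based
    permutational MANOVA on petal reflectance spectra, TMM normalization and
    negative-binomial exact-test differential expression with a rank-based
    fallback for low-expression genes, codon-aware detection of
    color-associated nonsynonymous SNPs from coding alignments, monophyly
    evaluation of labeled gene trees with bootstrap-support gating, a Monte
    Carlo label-randomization test of climate-niche divergence, and a
    rule-based aggregation of the evidence into hypothesis verdicts. Includes
    seeded generators for every input type with planted ground truth so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
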