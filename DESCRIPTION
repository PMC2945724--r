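Package: colorseeds
Title: Design and Certification of Spaced Seeds for SOLiD Color-Space Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing spaced seeds and position-restricted seed
    families for mapping SOLiD color-space reads. Builds probabilistic
    finite-state models of color-space read alignments (SNPs as adjacent
    color-mismatch pairs, period-5 reading-error structure, position-dependent
    error rates), computes exact seed-family sensitivity by dynamic programming
    over the product of a seed automaton and an alignment model, certifies the
    lossless property under mismatch, SNP/reading-error and indel-cost budgets
    with a minimal-cost dynamic program, and searches for good seed families by
    sampling and local optimization. Includes a synthetic color-read generator
    with csfasta/QUAL input and output and quality-correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
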