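Package: codonscope
Title: Dissecting Mutational and Selective Components of Codon Usage Bias
Version: 0.9.0
Authors@R:
    person("codonscope", "contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for separating the mutational and selective
    (transcription- and mRNA-structure-linked) components of synonymous
    codon usage bias in compact eukaryotic genomes. Implements
    sequence-intrinsic indices (codon complementarity, three-base
    periodicity, CAI, Fop, CBI, Nc), codon-level association with
    transcript abundance including back-calculation of expression from
    codon composition, PARS-based structural scoring of codons,
    intron folding-energy association analysis, four seedable
    sequence-randomization null models with Z-score machinery, a
    binning/coherence framework relating synonymous-fraction
    trajectories across gene properties, and a synthetic-genome
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
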