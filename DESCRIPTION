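Package: hybridase
Title: Genome-of-Origin Transcript Attribution in Cell-Fusion Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which donor genome a transcript came from in
    inter-cellular fusion hybrids, using allele-specific expression at
    discriminating SNPs. Simulates tetraploid (2+2) or octaploid (4+4) hybrid
    transcriptomes with known ground truth, removes anchor-primer
    contamination by in-silico BstUI digestion, aligns short reads to a
    transcript reference with a seed-and-extend ungapped aligner, builds
    per-site pileups and consensus genotype calls, selects discriminating
    SNPs (homozygous-different or heterozygous in exactly one donor), and
    attributes reads to donor genomes with copy-number weighting. Includes
    quantile normalization and Pearson correlation utilities for expression
    profiles, and a scenario test that distinguishes a transcriptionally
    reprogrammed adopted genome from silent cargo.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
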