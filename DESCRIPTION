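Package: coremk
Title: Core-Genome McDonald-Kreitman Tests of Adaptive Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide McDonald-Kreitman analysis for prokaryote core
    genomes. From per-gene codon alignments of single-copy orthologs the
    package counts synonymous and non-synonymous polymorphisms and fixed
    differences by shortest stop-free mutational pathway averaging, computes
    the per-gene Neutrality Index and Direction of Selection statistics with
    contingency-table significance tests, and pools genes into the
    Tarone-Greenland weighted Neutrality Index with a seeded bootstrap
    confidence interval. Supporting stages cover alignment trimming and
    quality control, UPGMA trees on concatenated orthologs with automatic
    outgroup designation from the first split, per-gene tree congruency
    filtering, the pairwise homoplasy index permutation test for
    recombination, site-frequency spectra and nucleotide diversity, and a
    seeded forward simulator of core-genome ortholog sets with known
    selection regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
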