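Package: plastorate
Title: Substitution Rates and Genome Rearrangement in Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links plastid protein-coding-gene substitution rates to genome
    architecture. Implements pairwise dN/dS estimation by the Nei-Gojobori
    (1986) counting method with Jukes-Cantor correction, the Goldman-Yang
    single-ratio codon model (M0) fitted by maximum likelihood on a fixed tree,
    likelihood-ratio tests for nested site models, exact signed reversal
    (inversion) distances between locally collinear block orders via the
    Hannenhalli-Pevzner breakpoint-graph formula with a breadth-first-search
    oracle, in-frame indel counting against a reference taxon, and the
    correlation stage: Pearson tests with Bonferroni correction and
    phylogenetic generalized least squares under Brownian-motion covariance.
    A synthetic-data module generates complete datasets (tree, codon
    alignments, signed block orders, indels, feature tables) with a tunable
    planted correlation between branch substitution rates and rearrangement
    intensity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
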