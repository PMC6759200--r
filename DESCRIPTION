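Package: condevo
Title: Molecular Evolution of Condensin Complexes: Loss Mapping,
    Homology Screening, and Tests of Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary dynamics of condensin and
    related SMC complexes across large phylogenies. Implements a tiered
    homology-search protocol for calling gene presence or absence from
    genome sequence, a duplication screen with sequencing-artifact
    filtering and reciprocal-best-hit validation, Dollo-parsimony mapping
    of independent gene-loss events onto a rooted species tree, the
    unpolarized McDonald-Kreitman test with codon pathway counting
    (alpha and Fisher's exact p-value), likelihood-ratio tests comparing
    neutral and positive-selection codon site models with Bonferroni
    thresholds, Wilson score intervals for chromosome-pairing proportions,
    and maximum-density window selection for oligo FISH probe design.
    A synthetic-data module generates genomes, codon alignments, loss
    histories, and pairing counts with known ground truth so every stage
    can be exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
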