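Package: trnafeat
Title: Consensus Features, Distributions and Position-Specific Scoring of
    Sprinzl-Aligned tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of transfer RNA gene sets on the
    standard Sprinzl coordinate system: curation filtering of tRNAscan-SE
    predictions, nucleotide and base-pair distributions grouped by clade,
    isotype, anticodon and bit-score focus, tiered IUPAC consensus-feature
    calling with component and combined frequency thresholds, clade-versus-
    domain consensus comparison, and position-specific log-odds penalty
    scoring of query tRNAs against a reference profile.  Includes readers and
    writers for Sprinzl-dialect Stockholm alignments, tRNAscan-SE tabular
    output, taxonomy tables and Newick subtrees, a deterministic synthetic
    fixture generator, and exportable cloverleaf, tilemap and bitchart data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
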