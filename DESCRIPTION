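Package: dyadsel
Title: Positive Selection of Amino-Acid Dyads by Neutral-Evolution Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether a two-residue motif (dyad) is selectively
    maintained in a protein domain family even when its position is not
    conserved in the alignment. Builds a reversible continuous-time Markov
    substitution model equivalent to the BLOSUM62 score matrix, simulates
    neutral evolution of a root sequence down a rooted phylogeny, and
    compares the observed number of motif-bearing sequences with the
    empirical Monte-Carlo null distribution, including a 400-dyad
    cross-validation scan. Also profiles single-residue and dyad
    compositions of proteome FASTA collections and their log-odds, and
    generates synthetic neutral and selection-constrained benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
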