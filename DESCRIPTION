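Package: editscan
Title: De Novo Detection and Quantification of A-to-I RNA Editing in an
    Editing-Naive Genome
Version: 1.0.0
Authors@R:
    person("editscan", "developers", email = "maintainer@editscan.dev",
           role = c("aut", "cre"))
Description: Tools for studying adenosine-to-inosine (A-to-I) RNA editing
    imposed on an editing-naive genome such as Saccharomyces cerevisiae
    expressing a heterologous ADAR. Provides a truth-aware simulator of
    genomes, planted editing sites and unstranded RNA-seq/DNA-seq reads;
    de novo editing-site detection from RNA/DNA pileups with an exact
    binomial error test and genome-scale Benjamini-Hochberg correction;
    genome-wide editing-index quantification, neighbour-nucleotide motif
    and replicate-recurrence summaries; a temperature-aware nearest-
    neighbour minimum-free-energy folder for the duplex substructures
    around edited sites; growth-assay quantification (OD600 area under
    the curve, spot pixel-density ratios) with significance-star
    labelling; and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
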