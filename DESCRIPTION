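Package: dgnet
Title: Signed Bipartite Disease-Gene Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, randomization and statistical analysis of signed
    bipartite disease-gene networks, in which an edge records whether a gene
    is up- or down-regulated in a disease. Provides a synthetic network
    generator emulating a multi-disease renal transcriptomic study (7
    diseases, 747 genes, gene degrees 1-5, full within-gene regulation
    concordance, degree-dependent down-regulation), three permutation null
    models (uniform rewiring, degree-preserving checkerboard swaps, sign
    label shuffling) with Monte-Carlo confidence envelopes and add-one
    permutation p-values, the per-degree down-regulation curve, and
    Fruchterman-Reingold force-directed layout in two and three dimensions
    with Pajek .net/.clu import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    e1071,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
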