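Package: orthodiverge
Title: Cross-Species Transcriptome Divergence of Orthologous Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies one-to-one orthologous transcripts between two species
    from reciprocal similarity-search hit tables, delineates and aligns their
    coding sequences codon-aware, classifies aligned sites by codon degeneracy
    and CpG context, estimates synonymous and nonsynonymous substitution rates
    (Nei-Gojobori counting and the Yang-Nielsen approximate method), calls
    differentially expressed orthologs from negative-binomial read counts, and
    tests gene sets for pathway over-representation. A codon-model sequence
    simulator with CpG hypermutability, fabricated hit tables, count matrices
    and planted pathway enrichment provides ground-truth fixtures so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
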