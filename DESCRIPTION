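Package: holotome
Title: Dissecting a Coral Holobiont Transcriptome into Host and Symbiont Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a mixed coral-dinoflagellate ("holobiont")
    transcriptome assembly sequenced from a single symbiotic colony. Contigs
    are classified as host or symbiont by exclusive alignment against two
    reference genomes with an e-value cutoff scan, and the split is validated
    by two-component Gaussian mixture modelling of contig GC content. Further
    stages re-implement the read and contig quality-control rules of the
    original study (quality trimming, pair-length filtering, PCR-duplicate and
    adapter removal, ORF-level redundancy removal), annotation-evidence
    accounting, reciprocal-best-hit orthology with alignment-coverage
    filtering, within-colony polymorphism estimation from filtered variant
    calls, ITS-2 marker read recruitment, greedy overlap assembly and symbiont
    typing, and KEGG-orthology-based inference of amino-acid biosynthetic
    complementarity between host and symbiont. A seeded synthetic-data
    generator produces truth-labelled holobiont datasets so the whole workflow
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
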