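Package: pylseeker
Title: Prediction of Pyrrolysine-Incorporating Genes from Amber-Interrupted
    Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate pyrrolysine (Pyl) incorporating genes in
    prokaryotic genomes. Scans both strands for amber-interrupted open
    reading frames (iORFs), clusters the translated 100-nt regions
    downstream of the in-frame UAG (putative PYLIS elements) by reciprocal
    translated homology, scores clusters with coding-potential, conservation
    and RNA-structure features, assesses each feature against a sampled
    mean-rank null distribution, and produces a weighted ranking of
    candidate gene clusters together with a neighbor-joining dendrogram of
    PYLIS structural similarity. Includes a synthetic-genome benchmark
    generator with planted homologous iORF families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
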