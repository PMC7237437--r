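Package: smithscan
Title: Discovery of Small Mitochondrial RNAs, Target Prediction, and
    Locus Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to annotate small mitochondrial highly-transcribed RNAs
    (smithRNAs) from small RNA sequencing libraries mapped to circular
    mitochondrial genomes: exhaustive mismatch-tolerant read mapping with
    nuclear decoy screening, abundance clustering, 5'/3' end-sharpness
    filtering, miRNA-style seed and duplex free-energy target prediction
    against 3' UTR sets, candidate naming and pre-region annotation, and a
    sliding-window nucleotide diversity analysis of locus conservation with
    Kruskal-Wallis, Dunn and Mann-Whitney tests. Includes synthetic-data
    generators for every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
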