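Package: antarscan
Title: Discovery of ANTAR-Target Dual Stem-Loop RNAs in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Profile-based scanning for ANTAR-target RNA elements: dual
    stem-loop motifs with hexanucleotide loops (conserved A1/G4) joined by a
    short linker, as found upstream of and within bacterial open reading
    frames. Builds a probabilistic motif profile from a seed alignment,
    enumerates and scores candidate dual hairpins across genomes, calibrates
    score thresholds against dinucleotide-preserving shuffled nulls,
    classifies hits by genomic context (intergenic, sequestering the
    ribosome-binding site or start codon, inside ORF), clusters hits at
    sequence-identity cutoffs and reports structure-conservation statistics
    (simplified folding energy, structure conservation index, folding
    z-scores, pairwise covariation). Includes a synthetic-genome simulator
    with planted motifs and full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
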