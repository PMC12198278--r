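Package: pseudocasp
Title: Gene-Structure Forensics for Pseudogene Detection in Caspase Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing how a gene loses protein-coding capacity.
    Computes splicing phases from exon/CDS gene models, performs from-scratch
    global and local pairwise alignment with affine gaps, calls indels against
    an intact ortholog, propagates frameshifts to locate premature termination
    codons, evaluates whether exon skipping can rescue the reading frame, maps
    rescue open reading frames onto the ortholog protein, checks conservation
    of the caspase catalytic His/Cys dyad, and detects intragenic domain
    duplication by self-alignment with permutation significance and exon
    attribution. A seed-reproducible generator builds caspase-16-like loci
    (11 exons, internally duplicated domain, controlled lesions and ortholog
    divergence) with truth manifests so the whole pipeline is testable without
    any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
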