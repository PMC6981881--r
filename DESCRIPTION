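Package: cryptarget
Title: Non-Coding RNA Regulation Screens for a Kelp Blue-Light Receptor
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the non-coding RNA regulatory context of a
    focal gene from sequence and expression data, developed around the
    cryptochrome CRY-DASH of the kelp Saccharina japonica. Implements
    plant-style microRNA target prediction on ungapped miRNA:mRNA duplexes
    (weighted mismatch counting with G:U wobbles as half mismatches, seed-region
    and central-region filters, and a nearest-neighbor hybridization
    free-energy ratio against the perfect complement), small-RNA read
    composition summaries with a maximum base-pairing hairpin fold for
    precursor validation, positional classification of long non-coding RNAs
    against protein-coding annotation with cis- and trans-target screens,
    relative qPCR quantification by the 2^-ddCt method with circadian profile
    and peak-periodicity summaries, expression clustering, and assembly of
    miRNA-gene-lincRNA and competing endogenous RNA (ceRNA) networks. Seeded
    generators produce synthetic inputs with the planted structure each stage
    assumes, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
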