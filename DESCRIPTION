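Package: dupscreen
Title: Genome Curation and Whole-Genome Duplication Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a chromosome-scale
    invertebrate genome project: taxonomic scaffold decontamination by
    majority vote, multi-round reconciliation of ab initio gene models with
    full-length transcript evidence, integrity assessment of conserved
    homeobox gene clusters (including detection of missing members such as
    the Hox gene abdominal-A), and a genome-wide self-synteny Oxford-grid
    screen for whole-genome duplication signatures built from an all-vs-all
    protein self-alignment.  A synthetic genome and evidence simulator with
    known ground truth exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    graphics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
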