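Package: chromosel
Title: Selection Analysis of Chromodomain-Containing LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural annotation of chromodomain-containing Gypsy (chromovirus)
    LTR retrotransposons (paired LTRs with TG...CA termini, target-site
    duplications, primer-binding site, polypurine tract, Gag-Pol domain order),
    motif-based chromodomain group I/II classification, neighbor-joining
    phylogenetics with bootstrap support, and inference of positive selection on
    labeled branches via codon site-class models (M0, M1a, branch-site model A
    and an extended clade model C) with likelihood-ratio tests against
    chi-square and boundary mixture nulls, Hommel family-wise error correction,
    and empirical-Bayes identification of positively selected sites. Includes a
    synthetic-data generator (codon alignments evolved under the site-class
    regimes along labeled trees, and toy genomes with planted elements) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pROC,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
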