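Package: premirscan
Title: Haplotype-Aware Discovery of Putative Pre-miRNA Hairpin Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An exhaustive sliding-window scanner for putative pre-miRNA
    hairpin loci in haplotype-resolved genomic sequence, built around a
    self-contained nearest-neighbor minimum-free-energy folding engine with
    dot-bracket loop decomposition. Candidate windows are filtered by free
    energy and hairpin topology, screened against exon annotations, and
    merged into a locus atlas. Downstream analyses cover exact-match
    haplotype conservation of mature and precursor sequences, semi-global
    alignment of novel mature miRNAs against annotated catalogs, Argonaute
    CLIP-seq read-support counting, Dicer-dependence calls from qPCR delta-Ct
    tables, and intersection of miRNA loci with linkage-disequilibrium blocks
    around disease-associated SNPs. Seeded simulators generate every input
    the pipeline consumes, with planted ground truth, so all stages are
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
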