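Package: haplotangle
Title: Haplotype-Aware De Novo Diploid Assembly by Graph Untangling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale de novo assembly of both haplotypes of a diploid
    genome from short-read data. Builds a de Bruijn graph with increasing
    k-mer sizes while keeping heterozygous bubbles, phases heterozygous
    variants by untangling cross structures with paired-end, mate-pair,
    long-read and linked-read (barcode) evidence, scaffolds with multiple
    libraries, applies haplotype synteny-based correction anchored on
    simple bubbles, closes gaps by local assembly, and optionally builds
    consensus scaffolds. Ships a diploid genome and read simulator with
    tunable heterozygosity and highly divergent regions (HDRs), and the
    full phasing-evaluation toolkit: NG50/LG50 assembly statistics,
    heterozygous 1k-mer pair construction, fragment-based recall and
    precision, per-window phased-pair rates, reference-absent bubble
    screening, and switch-error counting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
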