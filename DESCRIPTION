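Package: barcodegap
Title: Barcode-Gap Analysis and Threshold-Based Species Delimitation for
    COI Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based assessment of species limits from aligned DNA
    barcodes (cytochrome c oxidase subunit I). Implements Kimura 2-parameter
    and p-distances with pairwise deletion of gaps and missing data,
    sequence quality control (length, ambiguous-base and stop-codon checks),
    haplotype collapsing, species-level barcode-gap summaries and anomaly
    flagging, neighbour-joining trees with nonparametric bootstrap support
    and monophyly assessment, single-linkage clustering over a sweep of
    divergence thresholds with lumping/splitting error rates and richness
    estimation, replayable taxonomic-reassessment change sets, locality
    permutation tests, and a seeded generator of synthetic barcode data
    with planted anomalies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
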