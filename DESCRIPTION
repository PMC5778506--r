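Package: apaseq
Title: Cleavage-Site Calling and Alternative Polyadenylation Analysis for 3'-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing 3'-end sequencing (3'-Seq) data: detection of
    untemplated poly(A) tails in aligned reads with an internal-priming guard,
    cleavage-site (CS) calling from per-gene CS profiles under support and
    spacing rules, polyadenylation-signal (PAS) hexamer positional enrichment
    around called sites, per-3'UTR differential CS-usage testing (chi-square
    with Benjamini-Hochberg FDR control), the Proximal Usage Index (PUI) and
    global 3'UTR shortening/lengthening trend assessment. Includes a fully
    deterministic synthetic 3'-Seq data generator (genome, gene models,
    aligned reads with ground truth) so that every stage is testable at desk
    scale, plus auxiliary RNA-seq fold-change (RPKM, quantile normalization,
    expression floor) and IP-MS interactor-selection utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
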