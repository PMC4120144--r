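Package: randalign
Title: Randomized Seed-and-Extend Alignment of Short Reads to Reference Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns single-end DNA sequencing reads to a reference genome with a
    randomized seed-and-extend strategy. Two FM indices (one over the genome, one
    over its reverse) support bidirectional maximal exact matching anchored at a
    random read position; seeds are extended under a bounded edit distance with
    early pruning. The distance bound t, minimum seed length W and attempt count A
    are derived from the read length and per-base error rate via a binomial error
    model. Includes a wgsim-style read simulator with indel polymorphisms, a
    precision/recall/misalignment evaluator with positional tolerance, and a
    k-mer repeat-density statistic of genome complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
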