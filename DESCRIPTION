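Package: magicMAE
Title: Inference of Mosaic Monoallelic Expression from Gene-Body Chromatin Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers mosaic monoallelic expression (MAE) of autosomal genes from
    H3K27me3/H3K36me3 gene-body ChIP-Seq signal using an alternating decision
    tree classifier trained on quantile-ranked, input-normalized signal
    (the MaGIC procedure), together with length, expression and dataset
    dynamic-range filters. Validates chromatin-based calls against
    allele-specific RNA-Seq (exact binomial test with Benjamini-Hochberg
    correction plus a binomial TOST equivalence test), quantifies cross-species
    conservation of MAE over one-to-one orthologs with a hypergeometric overlap
    test, clusters MAE profiles across tissues with Gower distance and UPGMA,
    and corrects multi-sample MAE counts for imperfect classifier accuracy.
    Includes simulators for every input so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
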