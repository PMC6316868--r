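Package: bblockr
Title: B Chromosome Sequence Detection from Read-Depth Coverage Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects B-chromosome-derived sequence from whole-genome
    resequencing depth of individuals with and without a supernumerary B
    chromosome. Per-base read depth is scaled by genome-wide mean depth,
    the scaled coverage ratio (SCR) between a B carrier and a B-lacking
    reference is combined with an exact binomial test, and significant
    positions are merged and filtered into "B blocks". Blocks are
    intersected across samples into a multi-sample core set, per-block
    B-located copy numbers are estimated from coverage ratios, and totals
    are reported both on the reference ("A space") and weighted by copy
    number ("B space"). Includes gene-overlap reports against BED/GFF3
    annotations and a coverage simulator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
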