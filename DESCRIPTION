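Package: bsaskit
Title: Targeted Bisulfite Amplicon Sequencing Analysis for Sex-Gene Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted bisulfite amplicon sequencing (BSAS) studies of
    DNA methylation in fish gonads: amplicon panel bookkeeping with TSS-relative
    coordinates, in-silico bisulfite conversion and reference building, bisulfite
    PCR primer validation, a seeded simulator of directional bisulfite amplicon
    reads and RT-qPCR Ct tables, a bisulfite-aware amplicon quantifier producing
    per-CpG methylation matrices with conversion-efficiency QC, Kruskal-Wallis
    group statistics with Dunn post-hoc compact letter displays, 2^-deltaCt
    relative-expression analysis, and virtual RT-PCR prediction of sex-specific
    splice-variant assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    car,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
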