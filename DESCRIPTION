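Package: sportmethyl
Title: Methylome and Transcriptome Comparison of Fruit-Tree Bud Sports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing the whole-genome bisulfite-sequencing methylome and the
    RNA-seq transcriptome of a fruit-tree cultivar against its bud-sport mutant.
    Provides context-resolved (CG/CHG/CHH) methylation quantification, sliding-window
    differential-methylation calling with a two-sided Fisher exact test, gene-body and
    promoter annotation of DMRs, nonparametric differential-expression calling by fold
    change and divergence probability, methylome-transcriptome integration, flat
    gene-set enrichment with Bonferroni correction, pH-differential anthocyanin
    quantification and 2^-ddCt relative expression, plus a synthetic-data generator
    with planted truth so that the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
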