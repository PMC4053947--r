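Package: tdmrseg
Title: Tissue-Specific Differentially Methylated Region Detection by
    Minimum-Description-Length Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects tissue-specific differentially methylated regions
    (tDMRs) on Infinium 450K-style beta-value matrices. Probes are grouped
    into runs bounded by 3 kb inter-probe gaps, each run is partitioned into
    blocks of homogeneous methylation dynamics by minimising a two-part
    minimum-description-length criterion with dynamic programming, and every
    block of three or more probes is tested for one-versus-rest tissue
    differences by ANOVA with Bonferroni control. Also provides invariant
    methylation classification, gene-region and CpG-island summaries, tissue
    clustering, tissue-versus-individual variance decomposition,
    methylation-expression correlation tables, and a seeded simulator of
    450K-like data with planted tDMR ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
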