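Package: fcpg
Title: Single-Cell 5-Formylcytosine (5fCpG) Calling and Landscape Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies 5-formylcytosine at CpG dyads (5fCpG) in single cells
    from chemical-labeling C-to-T conversion sequencing count tables. Labeling
    efficiency is calibrated from spike-in model DNA and the random C-to-T
    background from unmodified lambda DNA; per-cell calls combine candidate
    and noise site pools, SNP masking, an exact binomial test against the
    lambda background with Holm-Bonferroni correction, and unmodified-CpG
    calls. Downstream landscape statistics cover 5fCpG levels by genomic
    scope, relative enrichment over annotated elements and repeat subfamilies,
    windowed cross-cell variance, stage merging and transition accounting,
    shared marked regions, paired-sample differences, Spearman correlation
    clustering, signal metaplots around site centers, and matched-control
    repeat comparisons. A synthetic count generator with ground truth
    validates the whole pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
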