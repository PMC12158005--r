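Package: phasnet
Title: Plant Small RNA Annotation and miRNA-phasiRNA-mRNA Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plant small RNA annotation and
    post-transcriptional network inference: cleaning and collapsing of
    sRNA-seq reads, mismatch-tolerant genome alignment of tag stacks,
    MIR locus calling from mature/star duplex evidence, detection of
    21- and 24-nt PHAS loci by hypergeometric phasing statistics and
    phasing scores, trigger-miRNA assignment by penalty alignment,
    Allen-score/MFE-ratio target prediction for miRNAs and phasiRNAs,
    degradome (PARE) validation of cleavage sites with CleaveLand-style
    site categories, RP10M normalisation and reproductive-vs-vegetative
    differential expression, and classification of miRNA-PHAS-mRNA
    regulatory triples into miRNA-only (Model 1) and miRNA+phasiRNA
    (Model 2) modes. Ships a fully seeded synthetic-data generator with
    machine-readable ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
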