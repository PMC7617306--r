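Package: clonefate
Title: Clone-Fate Analysis of DNA-Barcoded Tumour Cells Under Immune Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cellular DNA-barcode lineage tracing of tumour cells
    co-cultured with cytotoxic effector cells. Extracts 21-nt barcodes from
    raw amplicon reads between fixed anchor sequences, restricts counts to a
    viral-library reference, merges technical replicates, applies detection
    filters, and computes clone-level statistics: Shannon diversity, a
    max/min variability statistic across replicate wells, and a
    negative-binomial differential-abundance test with Benjamini-Hochberg
    correction. A rule-based decision tree then assigns each clone one of
    five fates (eliminated, primary resistant, static, secondary resistant,
    other). A fully parameterised synthetic co-culture generator produces
    barcode libraries, count matrices and raw FASTQ reads with ground truth
    retained, so every pipeline stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
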