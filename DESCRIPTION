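Package: homeopipe
Title: Subgenome-Aware Expression and Variant Analysis for Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing accessions of an allopolyploid species at the
    level of its parental subgenomes. Provides a synthetic allopolyploid study
    generator with full ground truth (diverged homoeologous transcript sets,
    accession genotypes, expression truth, paired-end reads), k-mer based
    assignment of read pairs to subgenome and gene, FPKM quantification and
    differential expression between accessions, permutation and exact tests for
    enrichment of coordinately regulated homoeologous pairs among the
    differentially expressed genes, subgenome expression-dominance ratios,
    transcript-space SNP calling with multi-way shared/private partitioning
    against a reference panel, chi-square tests for SNP density in gene sets,
    and Fisher exact term enrichment with a stress-category report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
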