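Package: imprintcons
Title: Comparative Sequence-Conservation Analysis of Imprinted and Autosomal Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing sequence conservation
    around imprinted and biallelically expressed genes. Builds merged gene
    models from transcript annotations, partitions chromosomes into exonic,
    intronic, intergenic and promoter regions, classifies scored conserved
    elements (phastCons-style "most conserved" segments) against gene models
    and annotation tracks (CpG islands, repeats, transcription-factor binding
    sites), computes CpG-centred composition statistics including the
    (TpG+CpA)/(2*CpG) deamination index, performs two-group Wilcoxon and
    chi-square/Fisher comparisons with a significance-tier convention and
    random-gene-set background calibration, and scores k-mer motif enrichment
    against genomic background. Ships a synthetic-genome generator that emits
    internally consistent FASTA/GTF/BED bundles with planted group effects so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
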