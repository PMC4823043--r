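Package: ripchip
Title: Ago2 RIP-Chip miRNA Targetome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Argonaute-2 RNA immunoprecipitation
    microarray (Ago2 RIP-Chip) experiments that identify miRNA target
    genes. Provides quantile normalization and probe quality filtering for
    two-color array signal tables, immunoprecipitated-versus-total (IP/T)
    fold-enrichment statistics, targetome and miRNA-specific target
    calling, miRNA seed-site scanning of 3'UTR/CDS sequences, preranked
    gene-set enrichment with a permutation null for binding-site motif
    sets, mixed-model analysis of GFP competition growth assays, and a
    synthetic-data generator that plants ground-truth targets so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    fgsea,
    jsonlite,
    lme4,
    lmerTest,
    limma,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
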