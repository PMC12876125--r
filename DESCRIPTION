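Package: lrtalk
Title: Inter-Tissue Ligand-Receptor Crosstalk Mapping from Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers molecular communication between two tissue compartments
    (peripheral blood and synovium in case/control osteoarthritis cohorts)
    from bulk expression matrices. Provides quantile-normalization and PCA
    quality control, per-gene Welch and empirical-Bayes moderated t
    differential expression, classification of differentially expressed
    genes into ligands and receptors against a curated ligand-receptor pair
    database, construction of the directed within- and between-tissue
    communication map, hypergeometric over-representation analysis of
    differential ligands, and a synthetic two-tissue study generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
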