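Package: arcvir
Title: Random-Forest Classification of Archaeal Viruses from Metagenomic Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns each pre-identified dsDNA viral contig a probability of
    being an archaeal virus rather than a bacteriophage. Builds a 27-column
    per-contig feature table from gene calls and three kinds of filtered
    homology evidence (protein-vs-protein, profile-HMM, and iterative-profile
    searches against user-supplied reference sets), prunes co-correlated
    features, trains a random forest with recursive feature elimination by
    Gini importance, and reports per-contig vote-fraction probabilities.
    Also provides the legacy homology-rule classifier it supersedes, a
    from-scratch metric engine (TPR, specificity, accuracy, Matthews
    correlation, false discovery rate, ROC and precision-recall curves),
    dataset-perturbation benchmarking (size fractionation, microbial
    contamination spiking, subsampling), and a seeded synthetic-data
    generator so the whole pipeline is testable offline.
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
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
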