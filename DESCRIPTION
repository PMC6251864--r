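Package: m5cpred
Title: Tissue-Aware Prediction of RNA 5-Methylcytosine Sites from Sequence Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting RNA 5-methylcytosine (m5C) sites from the
    nucleotide sequence flanking candidate cytosines. Provides readers for
    transcript FASTA and site-annotation tables, fixed-width window extraction
    with explicit edge padding, one-hot and physicochemical ("Feng-style")
    sequence encodings, construction of class-imbalanced training sets and
    1:all independent test sets (including cross-tissue sample exclusion),
    random-forest and baseline classifiers, false-positive-rate calibrated
    stringency thresholds, ROC/AUC evaluation from first principles, an
    intra-/inter-tissue benchmarking matrix, and a synthetic motif-implantation
    data generator so the whole pipeline is exercisable without external data.
    All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
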