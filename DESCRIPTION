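Package: panprog
Title: Pan-Cancer Prognosis Analysis of Non-Coding RNA Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects prognosis-related miRNA and lncRNA markers per cancer
    type from log-scale expression and overall survival, builds naive-Bayes
    pan-cancer prognosis (PCPA) classifiers on spatially stratified
    train/test splits, evaluates them with ROC/AUC, Kaplan-Meier curves and
    the log-rank test, summarises cross-cancer marker sharing, profiles
    marker regulation of refined canonical signaling pathways, and runs a
    marker-oriented counterfactual simulation (MOS) that flags
    prognosis-alternative miRNAs and candidate drug-target genes. Ships a
    synthetic pan-cancer generator with planted survival-linked markers so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    e1071,
    nnet
Config/testthat/edition: 3
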