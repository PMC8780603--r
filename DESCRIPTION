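Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous reporting data, built around the reporting odds
    ratio (ROR). Reads quarterly "$"-delimited ASCII tables (DEMO, DRUG, REAC,
    THER, INDI), removes duplicate rows, joins reports to drugs, therapy dates
    and reactions, restricts to reactions occurring inside the therapy window,
    and cleans demographics. Per-drug RORs with Wald confidence intervals and
    two-sided Fisher exact p-values feed volcano plots and threshold-based
    candidate extraction; candidate drugs plus patient covariates enter
    stratified logistic risk models with Spearman collinearity screening and
    ROC-AUC. A bundled synthetic-data generator plants known drug-event odds
    ratios so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
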