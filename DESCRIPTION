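Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous reporting data, applied to drug-induced coagulopathies.
    Reads and writes quarterly "$"-delimited ASCII packages (DEMO, DRUG, REAC,
    OUTC, THER, INDI, RPSR), deduplicates follow-up reports into cases, flags
    event cases against a packaged MedDRA preferred-term dictionary for the
    coagulopathies high-level term, normalizes drug names and restricts to
    primary-suspect mentions, and computes three disproportionality statistics
    per drug and per therapeutic class: the reporting odds ratio (ROR) with
    Woolf 95% confidence interval, the proportional reporting ratio (PRR) with
    Pearson chi-squared, and the Bayesian confidence propagation neural network
    information component (IC) with Monte-Carlo credible bounds. A seeded
    synthetic reporting-system generator with planted drug-event relative risks
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
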