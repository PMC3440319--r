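Package: sarcsig
Title: Peripheral Blood Gene-Signature Discovery for Complicated Sarcoidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a peripheral-blood
    gene-signature discovery workflow for complicated sarcoidosis:
    permutation-based differential expression with a moderated d-statistic
    and q-value false-discovery-rate control, linear support-vector-machine
    recursive feature elimination with one-standard-error parsimonious
    signature selection and selection-frequency gene weights, repeated
    stratified cross-validated evaluation, hypergeometric pathway
    enrichment, cross-cohort signature transfer, and SNP-level case-control
    allelic association.  A synthetic-cohort generator with planted ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
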