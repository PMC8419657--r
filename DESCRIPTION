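Package: heatlag
Title: Temporal Heat Trends in Keyword Co-Occurrence Networks and
    Science-Policy Lag Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects significant temporal shifts ("heat variations") in the
    normalized total link strength of keyword co-occurrence networks built
    over expanding overlapping time windows of a bibliographic corpus,
    clusters item trajectories into trend groups, and measures the day lag
    between rising-heat periods of research clusters and the issuance dates
    of related policies.  Includes a MEDLINE-format reader, minimum-value
    multiple imputation for items absent from early windows, a left-tailed
    one-sample t trend test averaged over imputation iterations, average
    linkage clustering of Z-scored trajectories, wave-based policy alignment,
    and a synthetic corpus generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
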