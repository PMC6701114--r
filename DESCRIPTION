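Package: omescreen
Title: Pairwise Cross-Ome Interaction Regression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic pairwise association screening between two omes
    (microbial relative abundances and continuous immune readouts) across
    study cohorts. For every microbe-immune pair a full linear model with
    cohort-by-readout interaction terms is compared to a cohort-only reduced
    model with a partial F-test; results are adjusted with the
    Benjamini-Hochberg step-up procedure and assembled into a metrics-rich
    top table with per-cohort fitted-line geometry, DFFITS influence
    diagnostics, and a node-link network summary. Results export to a
    documented JSON document, a CSV top table, and a self-contained HTML
    report with inline regression microplots. A synthetic-data generator
    with planted per-cohort associations supports calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
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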