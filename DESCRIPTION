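Package: mindivsim
Title: Stochastic Simulation of Cell Division Timing in Escherichia coli With and Without the Min System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based population simulator of Escherichia coli cell
    growth, chromosome segregation and division timing, covering four model
    variants of increasing mechanistic detail: assigned division waiting
    times, effective blocking of division sites by a chromosome segregation
    defect (the minB deletion phenotype), polar/non-polar site equivalence,
    and competition of division sites for a limited pool of division
    machinery (FtsZ). Includes the observable statistics used to compare
    such models with single-cell microscopy data (waiting-time and
    inter-division-time distributions, cell-length distributions, division
    history classification, chromosome-cluster offsets) and a synthetic
    lineage-tracking generator so the whole analysis layer is testable
    without experimental data.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
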