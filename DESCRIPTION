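Package: gwcolony
Title: Branching-Process Analysis of Abortive and Clonogenic Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of colony-size distributions from colony formation
    assays using a Galton-Watson branching process in which each cell either
    undergoes reproductive cell death (RCD) with a generation-dependent
    probability P1(g) or divides. Provides the analytic colony-size
    probability model (Catalan closed form for constant P1 and a
    generation-indexed recursion for schedules), log-linear and log-log
    regression of size-frequency data with R-squared, AIC and 95% confidence
    limits, inversion of the smoothed distribution for P1(g) and the
    radiation-induced excess probability, a two-dimensional lattice Monte
    Carlo simulator of colony expansion with contact inhibition, and summary
    statistics linking abortive colony size distributions to the clonogenic
    surviving fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
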