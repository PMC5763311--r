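Package: tepcausal
Title: Detecting Directed Causality from Short Time Series via
    Topologically Equivalent Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects directed causal relations between variables observed as
    very short time series (around ten samples), as arise in time-course gene
    expression experiments. One scalar series per variable is lifted to a
    delay-coordinate (Takens) reconstruction of the shared attractor; the
    topologically-equivalent-position (TEP) score then measures how well the
    inter-point distance geometry of the putative effect's reconstruction
    predicts that of the putative cause, up to a similarity scale. Includes
    benchmark simulators (coupled logistic maps, a five-species coupled map,
    and a random gene-regulatory-network generator with Michaelis-Menten/Hill
    kinetics), ROC/AUC evaluation against ground-truth networks, delimited-text
    readers and writers, and tidy()/glance()/autoplot() methods for all result
    types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
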