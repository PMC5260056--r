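Package: pccmi
Title: Gene Regulatory Network Inference by Path-Consistency Conditional
    Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs undirected gene regulatory networks from expression
    matrices by scoring gene pairs with Gaussian mutual information, then
    pruning indirect edges whose conditional mutual information given common
    network neighbors falls below an interaction cutoff. The cutoff can be
    chosen automatically from the exponential decay of edge counts over a
    cutoff grid. Includes ROC/PR benchmarking against gold-standard edge
    lists, a linear-Gaussian synthetic network simulator for validation, and
    a command-line interface over tab-separated expression files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
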