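Package: tbnfuse
Title: Data-Fusion Learning of Transcriptional Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs genome-wide transcriptional regulatory networks by
    fusing a ChIP-Seq-derived TF binding network with gene-expression data
    under a linear-Gaussian Bayesian-network formalism. The binding network is
    turned into an acyclic starting model by iterative loop-breaking; the
    removed TF-TF arcs form a whitelist that constrains a correlation-guided,
    BIC-scored greedy structure search. Repeated search runs are distilled
    into a consensus network, from which a topological TF hierarchy (master
    regulators, middle managers, workhorses) is derived. Includes a synthetic
    data generator for loop-rich regulatory networks and linear-Gaussian
    expression, plus a robustness harness that injects false prior arcs and
    reports consensus precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
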