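Package: dynsfc
Title: Time-Resolved Structure-Function Coupling for Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how well a brain region's structural
    connectivity profile predicts its functional co-fluctuation profile at
    each imaging frame. Constructs edge time-series ("temporal unwrapping"
    of functional connectivity), builds structural predictor matrices
    (Euclidean distance, shortest path length on negative-log-transformed
    weights, weighted communicability), fits per-node per-frame multilinear
    regression models whose adjusted R-squared defines dynamic coupling,
    and summarizes coupling dynamics (coefficient of variation,
    dynamic-versus-static statistics, inter-node coupling similarity).
    Includes spatial autocorrelation-preserving spin permutation tests,
    robust correlation estimators (biweight midcorrelation, percentage
    bend), dominance analysis for predictor importance, and a synthetic
    data generator with known ground-truth coupling dynamics so that the
    full pipeline can be validated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
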