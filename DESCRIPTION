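Package: cpmr
Title: Connectome-Based Predictive Modeling of Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Connectome-based predictive modeling (CPM) of individual
    behavioral scores from functional connectivity edges. Builds Fisher-z
    partial- or Pearson-correlation connectomes from node time series,
    selects behavior-correlated edges into positive and negative predictive
    networks, fits per-tail linear models on summed edge weights, and
    evaluates prediction with family-aware (leave-one-family-out)
    cross-validation and permutation-based empirical p-values. Includes
    NEO-FFI questionnaire scoring, an elastic-net multivariate baseline,
    network-anatomy summaries (node degree, hubs, canonical-network
    overlap), and a synthetic-data generator with planted edge signal for
    end-to-end testing without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
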