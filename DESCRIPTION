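Package: reshapeRP
Title: Reshaped Random Projection Maximum-Entropy Models of Neural Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, sampling, and training of maximum-entropy models of
    binary neural population activity based on sparse nonlinear random
    projections. Supports the standard model in which Lagrange multipliers are
    learned over fixed random projections, "reshaping" in which the sparse
    projection weights themselves are tuned by gradient ascent, and joint
    (backpropagation-style) training, each optionally under biologically
    motivated synaptic constraints: a per-synapse ceiling, or homeostatic
    normalization of incoming, outgoing, or circuit-wide total synaptic
    weight. Includes exact enumeration for small populations,
    Metropolis-Hastings sampling and annealed-importance-sampling partition
    function estimation for larger ones, evaluation metrics (held-out
    log-likelihood, pattern-probability comparison, projection firing rates
    and correlations, synaptic budgets, rotation angles), and a seeded
    synthetic-data generator emulating 20 ms-binned cortical spike rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'constraints.R'
    'io.R'
    'projections.R'
    'model.R'
    'sampler.R'
    'synthetic.R'
    'metrics.R'
    'training.R'
    'experiments.R'
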