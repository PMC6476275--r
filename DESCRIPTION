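Package: metaphorspace
Title: Contextual Distributional Semantic Subspaces for Graded Metaphor Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds smoothed non-negative pointwise mutual information (PMI)
    co-occurrence matrices from plain-text corpora, projects dyad-specific
    low-dimensional subspaces by three dimension-selection techniques
    (independent, arithmetic-mean and geometric-mean PMI ranking), extracts a
    48-feature statistical geometry from each subspace, and maps those
    features to graded semantic judgements (metaphoricity, meaningfulness,
    familiarity) and metaphoric class via leave-one-out cross-validated
    linear and one-vs-rest logistic regressions with variance-inflation-factor
    constrained feature selection. Includes a static-embedding cosine
    baseline, deterministic synthetic corpus and rated-dyad generators, and a
    workbench that orchestrates the full experiment from a single
    configuration.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
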