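Package: memsem
Title: Time-Dependent Semantic Memory Transformation: Behavior, Model-Based
    RSA and Encoding-Retrieval Similarity
Version: 0.1.0
Authors@R:
    person("memsem", "maintainers", email = "memsem@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for delayed-recognition fMRI studies of
    time-dependent memory transformation. Scores recognition memory against
    semantically related, perceptually related and unrelated lures, classifies
    per-stimulus-set memory specificity (detailed, semantically transformed,
    perceptually transformed, forgotten), builds per-emotion representational
    similarity matrices (RSMs) from trial-wise voxel patterns with run-proximity
    bias correction, fits three a-priori conceptual model RSMs by Spearman rank
    correlation with Fisher z transformation, computes trial-specific
    encoding-retrieval similarity (ERS) and lure-based gist reinstatement, and
    provides the inferential layer (mixed ANOVA with Greenhouse-Geisser
    correction, Sidak-corrected contrasts, linear and generalized linear mixed
    models, outlier exclusion). A synthetic-data generator with item-specific,
    category-shared, run-offset and reinstatement pattern components makes the
    full pipeline runnable and testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
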