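Package: mdaBoost
Title: Metabolite-Disease Association Prediction with Similarity-Derived
    Features and Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts candidate metabolite-disease associations from a sparse
    binary association matrix, pathway memberships and disease-symptom
    catalogs. Builds four similarity matrices (pathway Hamming similarity for
    metabolites, symptom-entropy normalized mutual information for diseases,
    and Gaussian interaction profile kernels on both axes), integrates them,
    extracts statistical, graph-theoretic and nonnegative matrix factorization
    features per candidate pair, reduces them with PCA, and ranks pairs with a
    gradient-boosted classifier under leave-one-out and k-fold
    cross-validation. Also provides standalone, oracle-testable
    implementations of the gradient-based one-side sampling variance-gain
    estimator and exclusive feature bundling primitives, and a seeded
    planted-block synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
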