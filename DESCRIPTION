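Package: flavorwalk
Title: Food-Chemical Graph Embeddings from Recipe Co-Occurrence and
    Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Flavorwalk", "Developers", email = "maintainers@flavorwalk.dev",
           role = c("aut", "cre"))
Description: Builds a heterogeneous graph of food ingredients, flavor
    compounds and drug compounds from recipe co-occurrence statistics
    (normalized pointwise mutual information) and curated
    ingredient-compound relations; learns dense node embeddings with
    metapath-constrained random walks and skip-gram negative sampling,
    optionally augmented by a semi-supervised chemical structure
    prediction head over 881-bit substructure fingerprints; and
    evaluates embeddings by category clustering (normalized mutual
    information), cosine-similarity pairing recommendation, and
    thresholded compound-food relation prediction. Includes a
    deterministic synthetic-data generator with planted ingredient
    communities so the full pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
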