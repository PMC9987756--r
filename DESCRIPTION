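Package: kogatyper
Title: Oral-Gut Microbiome Typing, Co-Occurrence Networks and Health Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based typing of paired oral and gut 16S microbiome
    profiles: Jensen-Shannon divergence dissimilarities, deterministic
    partitioning-around-medoids clustering with Calinski-Harabasz and
    silhouette model selection, nested oral-to-gut composite typing,
    SparCC compositional correlation networks with permutation
    significance and seeded two-level co-occurrence extraction, and a
    z-score/percentile/quartile panel-scoring statistic for
    characterising the resulting community types.  Includes a
    Dirichlet-multinomial cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
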