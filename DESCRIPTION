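Package: transdx
Title: Transdiagnostic Symptom Profiling and Drug-Class Recommendation for
    Mental-Health Questionnaire Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical-decision-support toolkit for transdiagnostic analysis of
    mental-health questionnaire cohorts. Encodes mixed-type questionnaire items
    to a numeric feature matrix, clusters subjects by k-means and by Louvain
    community detection on a k-nearest-neighbour similarity graph with
    silhouette-based model selection, characterizes clusters (diagnosis
    composition flows, L1-penalized logistic feature importance, min-max
    category index scores), applies scale-threshold diagnosis rules and
    compares diagnosis sources, and recommends psychotropic drug classes by
    two engines: cluster prescription probabilities and an adaptive
    graph-neighbourhood recommender that expands breadth-first rings until a
    quota of prescription-labeled neighbours is met. Ships a synthetic cohort
    generator with known latent structure so the full pipeline is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
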