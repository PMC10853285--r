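Package: comorbclust
Title: Disease Cluster Discovery from Matched Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers clusters of medical conditions arising after an index
    diagnosis in person-level registry data. Builds sex- and birth-year-matched
    cohorts with incidence-density sampling, screens ICD-10 conditions with
    stratified Cox regression (PheWAS), quantifies comorbidity strength of
    disease pairs with relative-risk and phi-correlation statistics, partitions
    the comorbidity network into modules with the Louvain algorithm, orients
    pairs in time with binomial tests and nested case-control conditional
    logistic regression, merges the trajectory and module views into disease
    clusters, and computes per-patient cluster susceptibility scores. Includes
    a synthetic registry generator with planted cluster structure so every
    stage can be tested without access to protected registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    knitr
Config/testthat/edition: 3
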