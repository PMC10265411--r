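Package: acenet
Title: Disclosure Classification and Egocentric Network Analysis of
    Adverse Childhood Experiences on Social Media
Version: 0.1.0
Authors@R:
    person("acenet", "maintainers", email = "maintainers@acenet.invalid",
           role = c("aut", "cre"))
Description: A tested pipeline for studying web-based social networks of
    individuals who disclose adverse childhood experiences (ACEs).
    Provides text cleaning and keyword-query evaluation for short social
    media posts, a seeded embedding-plus-convolution text classifier
    whose softmax output is an ACE mention score, percentile-based
    aggregation of per-post scores into a per-user ACE alignment index,
    threshold-based sentiment profiling, reciprocity, restricted local
    clustering and homophily indexes on sampled directed egocentric
    follow networks, two-sided rank-sum group comparison with Bonferroni
    correction, and a synthetic-data generator with planted structure so
    every stage can be tested without platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
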