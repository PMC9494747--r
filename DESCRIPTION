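Package: danpsurvey
Title: DEMATEL-ANP Analysis of Expert Prioritization Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing expert pairwise-comparison surveys with a
    hybrid DEMATEL-ANP multi-criteria decision-making pipeline, as used to
    study how modelers prioritize input variables in staged model
    intercomparison protocols. Provides eigenvector priorities and
    consistency-ratio screening for reciprocal pairwise comparison matrices,
    total-relation influence analysis over variable categories, supermatrix
    limit priorities with stage-wise importance aggregation, tie-corrected
    Kendall concordance, Wilks' lambda group-difference testing, and the
    linkage between cumulative stage importance and ensemble prediction error
    (MER). Includes a synthetic survey generator with known ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
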