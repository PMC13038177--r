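Package: traitspace
Title: Trait-Space Analysis of Face Impressions and Group Stereotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the correlational structure of trait
    impressions ("trait spaces") varies across social groups and how it
    relates to stereotype knowledge. Builds per-group trait-pair correlation
    matrices from long-format Likert rating data, compares face-derived and
    stereotype-derived spaces with a mean-centered Spearman statistic
    (representational similarity analysis) with bootstrap and permutation
    inference, tests homogeneity of trait spaces across race-by-gender groups
    with a repeated-measures ANOVA including Mauchly's sphericity test and
    Greenhouse-Geisser corrections, and fits cross-classified multilevel
    models linking each perceiver's idiosyncratic stereotype associations to
    that perceiver's own face-trait space, with intraclass correlations and a
    model-implied variance (R-squared) decomposition. A synthetic-data
    generator with known ground truth (group-specific trait covariance,
    perceiver idiosyncrasy, tunable stereotype-face coupling, 1-7 Likert
    discretization) supports parameter-recovery experiments for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
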