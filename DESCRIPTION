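Package: saltscreener
Title: Construction, Scoring and Validation of a Dietary Sodium Screener
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a short food-frequency
    screener for dietary sodium. Derives consumption-weighted serving
    sizes and composite sodium values per screener item from a
    food-consumption table, scores participant responses into estimated
    daily sodium intake (mg/day) with optional reduced-sodium
    substitution, classifies intakes against the tolerable upper intake
    level, models repeated 24-h recall reference data (within/between
    person variance components and a shrinkage adjustment toward usual
    intake), and runs the full relative-validity and test-retest
    reliability battery: Bland-Altman limits of agreement with
    proportional-bias testing, paired t tests with effect sizes,
    de-attenuated correlations, Cohen's kappa with Landis-Koch bands,
    quartile cross-classification, Cronbach's alpha, skewness with
    standard error, boxplot outlier screening, and a limits-of-agreement
    sample-size calculation. A seeded synthetic cohort generator makes
    the whole pipeline testable without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
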