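Package: crpls
Title: Group Contrasts and Partial Least Squares Phenotyping of C-Reactive
    Protein in Depression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-sensitivity C-reactive protein (CRP) in
    stratified depression cohorts (treatment-resistant, treatment-responsive,
    untreated and healthy groups). Provides a seeded synthetic-cohort generator
    with planted latent structure; the planned between-group contrast battery
    (rank-sum, Student and Fisher-LSD t-tests, one-way ANOVA, Kruskal-Wallis,
    likelihood-ratio G-tests on the clinically elevated >3 mg/L threshold,
    Cohen's d, moment skewness and BMI residualisation of log10 CRP); a
    from-scratch univariate-response NIPALS partial least squares engine with
    variable importance in projection (VIP), leave-one-out PRESS factor
    selection and OLS-limit checks; and a two-step variable-selection workflow
    with bootstrap percentile confidence intervals for standardised
    coefficients and a resampling null for the percentage of variance
    explained. A command-line pipeline ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    e1071,
    emmeans,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
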