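Package: fosnet
Title: Brain-Wide c-Fos Density Screening, Functional Connectivity
    Networks, and Parvalbumin Co-Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for brain-wide immediate-early-gene
    (c-Fos) activity mapping studies in rodents. Provides a per-region
    negative binomial generalised linear model screen for c-Fos cell
    density under a stimulation-by-time factorial design (with Cook's
    distance influence exclusion, Benjamini-Hochberg control of the
    omnibus tests across regions, follow-up effects, percent change and
    direction banding), inter-regional Pearson correlation ("functional
    connectivity") networks with significance and false-discovery-rate
    edge filtering and signed network density statistics, and
    parvalbumin/c-Fos co-expression analysis with two-factor ANOVA and
    absolute Hedge's g effect-size profiles. A Gaussian-copula negative
    binomial cohort simulator with planted group effects and planted
    inter-regional (including negative) correlations makes every stage
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
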