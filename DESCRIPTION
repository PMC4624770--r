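Package: sadcea
Title: Cost-Utility Modelling of Interventions for Social Anxiety Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing 28 pharmacological,
    psychological and self-help interventions for adults with social anxiety
    disorder from a health-service perspective. Implements a 12-week treatment
    decision tree followed by a two-state (recovered / social anxiety disorder)
    Markov cohort model with half-cycle correction and annual discounting, a
    calibrated logistic-normal stand-in for the network-meta-analysis posterior
    of recovery probabilities, probabilistic sensitivity analysis, net monetary
    benefit, efficiency-frontier (extended dominance) analysis, and
    cost-effectiveness acceptability frontiers, plus deterministic scenario
    analyses for therapist banding, utilities, time horizons and relapse risk
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
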