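Package: rdsregsim
Title: Simulation and Evaluation of Regression Models for Respondent-Driven
    Sampling Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the validity of regression analysis of
    respondent-driven sampling (RDS) data by Monte-Carlo simulation.
    Generates networked populations with controlled size, outcome
    prevalence, homophily and a calibrated multimodal degree distribution;
    draws RDS samples with seeds, coupons and non-response; fits weighted
    and unweighted binomial and Poisson regression models with a range of
    clustering controls (recruiter-outcome covariates, generalized
    estimating equations, random seed intercepts) and cluster-robust
    sandwich variance estimators; and reduces the replicate fits to
    type-I error, confidence-interval coverage, relative bias and
    predictive accuracy.  Also provides naive, Salganik-Heckathorn (RDS-I)
    and Volz-Heckathorn (RDS-II) prevalence estimators with several
    confidence-interval constructions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
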