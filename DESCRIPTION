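Package: trapnet
Title: Bayesian Optimization of Pest-Monitoring Trap Networks
Version: 0.1.0
Authors@R:
    person("trapnet", "developers", email = "trapnet@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing which subset of candidate insect-trap
    locations to operate so that a Bayesian spatially-varying logistic
    growth model trained on the chosen sites best predicts cumulative
    pest counts at the unchosen sites. Provides the hierarchical growth
    model with Gaussian-process (exponential-correlation) fields for the
    asymptote and midpoint, kriging prediction at unobserved locations,
    the mean-log-error loss on held-out sites, a Bayesian-Optimization
    loop with a linear surrogate over binary site-inclusion vectors, a
    brute-force oracle, a Monte-Carlo experiment harness, and a
    synthetic-data generator emulating a multi-year weekly trapping
    schedule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
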