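Package: sevbf
Title: Severity-Aware Hypothesis Testing with Bayes Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how severely a statistical test probes its
    hypotheses, from both the error-statistical and the Bayesian
    perspective. Implements Mayo's post-data severity (SEV) for
    one-sided normal-mean tests with known standard deviation;
    encompassing-prior Bayes factors for interval-constrained
    hypotheses on two independent binomial success rates, with
    prior-predictive distributions and discrete highest-density-region
    plausibility checks; the expected absolute log-Bayes-factor as a
    pre-experimental measure of a design's evidential value, computed
    by exact lattice enumeration; and Monte-Carlo Bayes Factor Design
    Analysis (BFDA) for two-sample t-tests with the JZS default prior,
    returning rates of true, inconclusive, and misleading evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
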