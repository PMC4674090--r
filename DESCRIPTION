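Package: aacbdt
Title: Normative Behavioural Inhibition in Approach-Avoidance Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying behavioural inhibition -- the delay in
    initiating approach under threat -- as a cost-minimising strategy under
    Bayesian decision theory. Provides a decision model in which an agent
    trades an exponentially decaying reward opportunity against a subjective
    prior on temporally correlated threat, a simulator for an operant
    approach-avoidance conflict game (sequential reward tokens guarded by a
    Poisson-hazard predator), a trial-level behavioural analysis pipeline
    (implicit-choice reconstruction, latency filtering, condition means,
    random-intercept trend tests), and an ideal-observer inversion that
    reconstructs the implied threat prior from observed approach latencies
    and predicts latencies forward from the fitted prior.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
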