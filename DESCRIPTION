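Package: problearn
Title: Hidden-State Probability Learning and Prospect-Theory Choice Models
    for Bin-Sampling Gamble Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-stage bin-sampling gamble task in which payoffs
    are generated by hidden states (ball colors) whose probabilities must be
    learned from sequential draws, and models the resulting buy/pass choices.
    Provides Dirichlet-multinomial belief updating over hidden states or raw
    observations, a no-learning baseline, a delta-rule reinforcement
    forecaster, prospect-theory valuation with optional probability
    weighting, and softmax choice. Models are fit by multi-restart
    Nelder-Mead maximum likelihood and compared by BIC; parameter- and
    model-recovery studies quantify identifiability. Trial-wise uncertainty
    regressors (stimulus probability, prediction error, outcome entropy,
    choice entropy, net payoff) are derived and exported as event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
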