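Package: inducer
Title: Model-Based Adaptive Design for Intertemporal Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers probabilistic latent-variable delay-discounting models
    from binary choice data by bounded multi-start maximum likelihood,
    inverts the fitted response model in closed form to generate trials
    that induce prescribed choice probabilities, and validates models by
    two-run cross-validated binomial deviance, AIC, best-model counts,
    behavioural-homogeneity F-tests and test-retest reliability. Includes
    a zoo of eight discounting models, a synthetic Bernoulli-agent
    simulator for end-to-end protocol studies, and extensions to
    history-dependent Rescorla-Wagner learning and multi-categorical
    softmax responses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
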