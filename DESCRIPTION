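Package: seqsdt
Title: Signal Detection Models for Sequential Lineup Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gaussian signal-detection modelling of censored (and
    uncensored) sequential eyewitness lineup responses. Provides exact
    category probabilities under a factorial family of criterion and
    discriminability hypotheses, including target-rejection criterion
    shifts, confidence-rating extensions and a careless-responder
    mixture; maximum-likelihood fitting with G-squared, AIC and BIC
    model comparison and nested likelihood-ratio tests; multinomial
    simulation of homogeneous and heterogeneous witness populations;
    re-runnable power, parameter-recovery and selection-bias simulation
    studies; and expected-utility comparison of identification
    procedures. Ships the published choice-frequency tables from two
    large sequential lineup experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
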