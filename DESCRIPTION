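Package: perclearn
Title: Observer Model of Perceptual Learning with Efficient Coding and
    Conditional Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a probabilistic-population-code observer for
    near-horizontal motion direction: an efficiently-coded (warped) Poisson
    encoding population, a decoder unaware of the warping, maximum-a-posteriori
    discrimination with lapses, and Bayes-least-squares estimation conditioned
    on an implicit category decision. Perceptual learning is modelled as a
    Gaussian gain-modulation profile over the population. Includes per-observer
    fitting by a weighted L1 + energy-distance loss with a noise-tolerant
    evolution strategy, reduced-model variants and iterated k-fold
    cross-validated model comparison, nonparametric behavioural statistics
    (cluster-mass permutation tests on binned estimate counts, permutation
    AUROC with two-stage adaptive FDR, Gaussian-mixture modality
    classification), and a synthetic-study generator emulating a three-group
    pre/post training design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
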