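Package: spikecoding
Title: Neural Coding Schemes for Unsupervised Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing neural coding schemes in spiking neural
    networks. Implements four input spike encoders (Poisson rate,
    time-to-first-spike, phase, and burst coding), a two-layer leaky
    integrate-and-fire winner-take-all network trained with a simplified
    spike-timing-dependent plasticity rule, and a robustness/efficiency
    toolkit: input-noise models (additive white Gaussian noise, motion blur,
    reduced contrast), weight pruning, stochastic-rounding fixed-point
    quantization, synaptic programming noise and stuck-at-fault injection,
    plus spike/synaptic-operation accounting and a figure-of-merit for
    cross-scheme comparison. Includes a synthetic sparse-stroke image
    generator and an IDX-format reader so experiments run at desk scale or
    on MNIST-style datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
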