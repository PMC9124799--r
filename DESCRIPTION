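Package: snnfewshot
Title: Robust Few-Shot Learning in Recurrent Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of recurrent spiking neural networks
    (leaky integrate-and-fire, adaptive-threshold, and two-compartment
    dendritic neurons) with surrogate-gradient backpropagation through time
    and e-prop eligibility traces. Networks are optimized under a
    heterogeneous ensemble objective that combines a mixture-correntropy
    robust loss, cross-entropy, and firing-rate and membrane-voltage
    regularizers, with trainable combination weights constrained by an
    augmented Lagrangian. Includes a learning-to-learn architecture (a
    learner network receiving per-neuron learning signals from a teacher
    network), synthetic generators for noisy spatiotemporal spike-pattern
    classification, two-phase matching episodes, and two-joint-arm motor
    control tasks, and a command-line experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
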