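Package: hsichebb
Title: Three-Factor Hebbian Learning from an HSIC Information Bottleneck
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Layer-wise training of feedforward networks of rate-coded
    leaky-integrate neurons with a biologically plausible three-factor
    Hebbian rule derived from a kernel information-bottleneck objective.
    Provides Gaussian-kernel Hilbert-Schmidt Independence Criterion (HSIC)
    estimators, the working-memory ring buffer and layer-wise modulation
    signal that factorize the update into a local Hebbian term and a global
    per-neuron term, an auxiliary chaotic rate reservoir whose readout is
    trained by a least-mean-squares FORCE rule to reproduce the modulation
    signal, seeded synthetic dataset generators, and experiment runners
    with a cross-entropy output layer and a backpropagation baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
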