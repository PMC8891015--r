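Package: t4circuit
Title: Conductance-Based Modelling of Direction-Selective T4 Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical modelling and electrophysiological analysis tools for
    the Drosophila ON motion-vision pathway. Implements a passive
    single-compartment conductance model of a T4 neuron driven by its five
    columnar input classes (Mi9, Mi1, Tm3, Mi4, C3), including the supralinear
    interaction between cholinergic excitation and release from glutamatergic
    shunting inhibition; a passive multi-compartment cable model on SWC
    morphologies with an emulated proportional-integral voltage clamp;
    reverse-correlation receptive-field mapping and directional tuning
    statistics; current-clamp analytics (input resistance, time-locked
    resistance, alignment, leak subtraction); a synthetic-data generator that
    emulates the statistical structure of in vivo recordings; and
    likelihood-free parameter inference (bounded least-squares fitting and
    rejection-sampling posteriors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    lhs,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
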