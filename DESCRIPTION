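Package: hebbnet
Title: Competitive Hebbian Plasticity in Recurrent Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the self-organization of recurrent networks of excitatory
    and inhibitory rate neurons under Hebbian plasticity stabilized by
    synapse-type-specific competition for limited synaptic resources
    (divisive L1 weight normalization with separate excitatory and inhibitory
    resource pools). Provides the network dynamics and plasticity rules, an
    oriented-grating input model with configurable training protocols
    (including correlated and independent center/surround statistics), analysis
    metrics (tuning uniformity, preferred orientations, connectivity profiles,
    excitation-inhibition input decomposition, cross-orientation and surround
    suppression curves), and a linear fixed-point theory module (modified
    covariance, eigencircuit attraction, tuning-collapse condition) validated
    against brute-force linear algebra. Experiments are driven by named
    parameter presets or YAML configuration files and are fully reproducible
    from a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
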