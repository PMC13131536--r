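Package: ddpcm
Title: Discretized Diffusion Models for Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits and simulates models of continuous and discrete trait
    evolution on phylogenies by approximating stochastic diffusion with a
    nearest-neighbor continuous-time Markov chain on a binned trait space.
    Implements bounded and unbounded Brownian motion, the multi-state
    threshold model, a semi-threshold (censored) model, discrete-state
    dependent multi-rate and multi-trend Brownian motion, and a model of
    continuous-character dependent discrete trait evolution, together with
    forward simulators, exact small-tree reference computations, stochastic
    character mapping, and turnkey simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
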