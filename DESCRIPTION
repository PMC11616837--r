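Package: protospike
Title: Spike-Train Analysis of Chondroitin-Sulfate Modulated Proteinoid
    Microspheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for electrical spiking activity of proteinoid
    microspheres modulated by chondroitin sulfate clusters. Provides voltage
    trace input/output, robust threshold spike detection, descriptive spike
    statistics (moments, quartiles, kernel density estimates with Scott
    bandwidth), maximum-likelihood gamma amplitude models, Fano-factor
    variability analysis against theoretical renewal and rate-switching
    point-process references, Izhikevich neuron simulation with a
    configurable transduction stand-in and a signal-comparison battery
    (Welch t, Pearson r, Kolmogorov-Smirnov, cross-correlation lag),
    biophysical mechanism models (radial Poisson-Boltzmann electrostatics,
    Boltzmann channel gating, multi-conductance membrane dynamics, a
    concentration-dependent Hebbian rule), molecular-mechanics energetics
    bookkeeping, and a synthetic-data generator that emulates the
    statistical structure of the experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    deSolve,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
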