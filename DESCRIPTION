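Package: sweatsense
Title: Discrete Sweat Sensing: Simulation and Estimation of Active Sweat Glands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-based simulator of pulsatile eccrine sweat-gland droplet
    production sensed by a discretized (droplet-based) microfluidic device, and
    the signal-analysis algorithm that estimates the number of active sweat
    glands, and hence the per-gland sweat rate, from the sensed droplet-volume
    pulse train. Includes segmentation, integer volume quantization of merged
    droplets, exhaustive pattern decomposition with ambiguity classification,
    and scenario-level error-rate evaluation with bias-corrected and
    accelerated (BCa) bootstrap confidence intervals across device layouts,
    cycle times, and sweat rates.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
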