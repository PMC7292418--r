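Package: hepaltsim
Title: Virtual-Liver Simulation of Acetaminophen Hepatotoxicity and ALT
    Biomarker Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-event Monte Carlo simulation of acetaminophen (APAP)
    hepatotoxicity in a virtual mouse liver built from sampled hepatic
    lobule graphs with periportal-to-pericentral zonation.  Hepatocyte
    agents metabolize APAP, deplete glutathione, accumulate and mitigate
    damage products, and externalize the biomarker alanine
    aminotransferase (ALT) under four competing release mechanisms
    (necrosis only, mitochondrial-damage caused, non-mitochondrial-damage
    caused, and dual cause).  Includes a virtual-experiment harness for
    seeded multi-trial runs with per-band measurement agents, linear
    scaling of body ALT to plasma ALT with per-animal skew factors, and
    calibration utilities for the structural and kinetic defaults.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
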