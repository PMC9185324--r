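Package: brushwear
Title: Discrete-Element Simulation of Toothbrushing Abrasion on Tooth Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A three-dimensional discrete-element simulator of manual
    toothbrushing and the hard-tissue abrasion it produces. Flexible bristle
    tufts are modelled as worm-like chains of connected particles carrying
    stretching, bending and (optionally) torsion energies; contacts between
    bristles and against a simplified two-plate-plus-groove anterior tooth
    model follow the Hertz-Mindlin force law with Coulomb friction; sliding
    tip contacts accumulate Archard wear onto a discretised wear map of the
    tooth surface. Includes a quasi-static cantilever bench that validates
    the chain's bending response against the large-deflection elastica,
    scrub-stroke brushing runs over speed and depth sweeps, and wear-map
    summaries locating abrasion relative to the interproximal groove.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
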