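Package: phaflux
Title: Phase-Resolved Constraint-Based Flux Analysis of the PHA Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Contextualizes batch-culture physiology of
    polyhydroxyalkanoate (PHA) cycle engineered Pseudomonas putida strains
    into condition-specific constraint-based metabolic models. Converts
    time-course measurements (biomass, PHA content, free (R)-hydroxyalkanoates,
    octanoate) into per-phase specific rates, builds phase-wise flux balance
    analysis (FBA) models, reconstructs the full growth curve by dynamic FBA,
    samples each model's flux polytope with an artificial-centering
    hit-and-run Markov chain, and compares mutant versus wild-type median flux
    distributions. Ships a carbon-balanced octanoate/PHA core network and a
    synthetic physiology generator so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
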