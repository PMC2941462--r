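Package: dhtopo
Title: Dehydrons, Surface Curvature and Backbone Hydration of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects backbone hydrogen bonds in protein structures, counts
    side-chain nonpolar "wrappers" to flag solvent-exposed bonds (dehydrons),
    samples the solvent-accessible envelope and estimates signed
    osculating-sphere curvature radii near each bond, and computes hydration
    order parameters (closest-water distance, water-water hydrogen-bond
    coordination, and a coordination-difference action functional) from
    explicit-solvent coordinate frames. Includes deterministic synthetic
    generators for ideal peptides, tunable bond-wrapping environments,
    cavities of prescribed curvature, and water networks of prescribed
    coordination, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
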