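Package: rodaero
Title: Aerodynamics and In Vitro Assay Metrics for Elongated Inhalable Microparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes slip-corrected aerodynamic diameters of porous,
    nonspherical microparticles (cylindrical microrods and spheres) via the
    implicit dynamic-shape-factor relation with the Davies form of the
    Cunningham slip correction, including closed-form inversion for the shape
    factor from a measured mass median aerodynamic diameter. Provides
    cascade-impactor (Next-Generation Impactor) data reduction to MMAD, GSD
    and fine particle fraction by log-probit interpolation, plate-reader
    viability (MTT) and cytotoxicity (LDH) metrics with threshold
    classification, particle disintegration time-series summaries, empirical
    size-distribution statistics (d10/d50/d90, span), and seeded synthetic
    generators for every input format so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
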