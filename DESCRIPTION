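Package: asdphase
Title: Ternary Phase Diagrams and Loss-of-Release Prediction for Amorphous Solid Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Thermodynamic modeling of amorphous solid dispersion (ASD)
    dissolution behavior in water. Implements the PC-SAFT equation of state
    (hard-chain, dispersion and association contributions) to compute
    API/polymer/water activity coefficients, solid-liquid solubility lines,
    liquid-liquid binodal curves with tie lines, and spinodal loci of ternary
    drug/polymer/water systems. Couples the phase diagram with Gordon-Taylor
    glass-transition predictions (Simha-Boyer coefficients) to locate the
    "escape glass transition" (eGT) composition of the hydrating ASD surface,
    classifies drug-load-dependent loss of release into interfacial
    crystallization (Type I) and interfacial amorphous phase separation
    (Type II) mechanisms, and reports hydration-pathway crossing tables and
    drug-load thresholds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
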