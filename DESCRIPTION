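Package: pahgeom
Title: Geometric Descriptors and Stability Models for Polycyclic Aromatic Hydrocarbons
Version: 0.1.0
Authors@R: person("PAH", "Geometry Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes fast geometric descriptors of polycyclic aromatic
    hydrocarbon (PAH) structures from Cartesian (XYZ) coordinates --
    harmonic-oscillator model of aromaticity (HOMA) and its fused/edge
    variants, bond-length and bond-angle metrics, dihedral nonplanarity,
    pyramidalization, and maximal z-displacement -- and fits
    MAD-minimizing (least-absolute-deviation) linear models of
    isomerization energy on descriptor combinations.  Includes a
    synthetic benzenoid generator with controlled distortions so the
    whole pipeline is testable without external data, a fixed published
    three-descriptor predictor, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
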