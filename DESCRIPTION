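Package: hemeET
Title: Heme-to-Heme Electron Transfer Kinetics in Multiheme Cytochromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to extract nanosecond heme-to-heme electron-transfer (ET)
    rate constants in photosensitized multiheme cytochromes from pump-probe
    transient-absorbance data, and to place them on ET-theory distance rulers.
    Implements the photocycle kinetic network of a Ru-dye-labelled decaheme
    cytochrome (charge separation from three dye conformers, reversible
    three-heme hopping, charge recombination), solved by eigen-decomposition;
    seeded synthetic-data generators for transient-absorbance cubes,
    photoluminescence decays and potentiometric titrations; spectral
    quantification of species populations (370 nm triplet, 552 nm Q-band,
    475 nm ground-state bleach, Soret half-height-width analysis of His/Met
    versus His/His ferroheme); constrained multi-exponential and global
    kinetic fitting; Marcus and Hopfield rate expressions with
    free-energy-optimized rates and Moser-Dutton / Winkler-Gray rulers;
    Nernstian titration analysis; and heme-pair geometry (edge-to-edge
    distances, packing motifs) from PDB structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
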