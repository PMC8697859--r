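Package: spectroml
Title: Machine Learning of Spectroscopic Constants of Diatomic Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gaussian-process regression of equilibrium distances, harmonic
    vibrational frequencies and binding energies of heteronuclear diatomic
    molecules from periodic-table descriptors (group and period of the
    constituent atoms), together with the classical physics-based linear
    baselines and empirical bond-length/frequency rules they are compared
    against.  Includes a vendored element table, diatomic formula parsing,
    permutation-augmented feature construction, exact explicit-basis GP
    regression with exponential and Matern-5/2 kernels, a stratified
    Monte-Carlo train/test evaluation protocol with nested cross-validation,
    learning curves, and a synthetic-data generator that emulates the
    statistical structure of experimental constants tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
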