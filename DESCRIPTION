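Package: spidock
Title: Rescoring Protein Docking Decoys with Simulated XFEL Single-Particle Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hybrid structure-determination toolkit that combines X-ray free
    electron laser (XFEL) single-particle scattering with rigid-body docking.
    It simulates single-particle diffraction patterns from atomic models on
    the Ewald sphere by direct summation of atomic scattering factors, scales
    them to a realistic photon budget with Poisson and Gaussian background
    noise, and scores candidate complex structures (docking decoys) against a
    reference pattern set using single-particle (SPI) and small-angle
    scattering (SAXS) chi-scores, with brute-force orientation matching over a
    discretized Euler-angle grid.  Reduced pattern representations (radial
    profiles and angular auto-correlations) accelerate orientation matching by
    removing the in-plane rotation angle.  Ranking power is evaluated through
    RMSD or density-overlap (s-score) probability distributions, cumulative
    curves, and areas under the curve (AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
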