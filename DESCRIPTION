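Package: holocount
Title: Off-Axis Digital Holographic Microscopy Reconstruction, Volumetric
    Refocusing and 3D Particle Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical processing chain for off-axis digital holographic
    microscopy of particle suspensions in microfluidic chambers: Fourier-domain
    demodulation of the real-image term with a super-Gaussian window, Zernike
    aberration compensation, least-squares phase unwrapping, angular-spectrum
    volumetric refocusing with ringing-artifact suppression, and 3D
    segmentation-based particle counting.  Ships a seeded synthetic hologram
    generator (multislice thin phase objects plus a tilted reference wave) with
    full ground truth, and the analytic phase-noise/signal-to-noise model for
    suspended particles, including least-squares fitting of its concentration
    and chamber-height dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
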