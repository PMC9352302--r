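Package: fddcs
Title: Holographic Fourier-Domain Diffuse Correlation Spectroscopy Signal Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for multispeckle Fourier-domain diffuse
    correlation spectroscopy (FD-DCS) with off-axis holographic camera
    detection. Provides a physics-level simulator of heterodyne dynamic-speckle
    hologram stacks (Brownian-motion phantom, shot/read/quantisation noise,
    finite pixel fill factor, injectable mode hops and global clutter),
    holographic reconstruction with shot-noise-normalised power spectral
    density estimation, modulation-transfer-function correction and
    fill-factor calibration, singular-value-decomposition spatiotemporal
    clutter filtering, a sort-median-unsort multispeckle denoising algorithm,
    Lorentzian spectrum fitting, and speckle-statistics SNR analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
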