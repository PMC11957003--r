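Package: cryolabel
Title: Voxel-Wise Training-Label Generation and FSC Validation for Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning matched cryo-EM density maps and atomic models
    into voxel-wise training labels for map-enhancement models. Reads and
    writes MRC/CCP4 volumes with explicit origin and axis-order handling,
    resamples experimental maps to a 1 Angstrom isotropic grid, simulates
    idealized noise-free density from atomic coordinates by truncated
    Gaussian convolution, and emits three aligned label volumes: a masked
    regression target carrying simulated density, a three-class
    atom/neighbourhood/background segmentation, and a per-voxel atom-type
    map (C-alpha, C-beta, carbonyl carbon, oxygen, nitrogen). Label quality
    is validated with an unmasked Fourier Shell Correlation estimator at the
    0.143 and 0.5 thresholds. Includes dataset-curation filters for
    map/model manifests, resolution-stratified splitting, sub-cube
    extraction for patch-based learning, and a synthetic fixture generator
    (poly-alanine helices plus matched noisy maps) so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
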