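Package: plectotrack
Title: Detection and Quantification of DNA Plectonemes in Single-Molecule
    Kymographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, detection, tracking and quantification of plectonemic
    DNA supercoils in two-channel fluorescence kymographs of doubly-tethered,
    torsionally constrained DNA molecules.  Includes a ground-truthed synthetic
    image-stack generator emulating intercalator-stained DNA with diffusing
    plectonemes and a labeled, promoter-stalled RNA polymerase; a detection
    pipeline (median filtering, white top-hat background subtraction, kymograph
    construction, peak-peeling end localization, punctum detection, trajectory
    linking and intensity-based base-pair size calibration); summary statistics
    for twin-supercoiled-domain experiments (position-resolved densities,
    plectoneme count distributions, RNAP colocalization, upstream/downstream
    partition fractions, total-supercoil time series, diffusion constants and
    relaxation times); and a self-contained rotational-drag torque-balance
    model of supercoil induction by a translocating polymerase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
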