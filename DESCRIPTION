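Package: epimap
Title: Epicardial Electrogram Mapping, Frequency Analysis and Synthetic
    Multichannel Electrogram Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel unipolar epicardial
    electrograms recorded with high-density flexible electrode arrays:
    zero-phase bandpass conditioning, far-field ventricular QRS-T template
    subtraction, channel quality control and spatial interpolation,
    (dV/dt)max activation-time detection, 15-segment isochrone maps,
    time-lapse activation frames, local plane-fit conduction-velocity
    estimation, earliest-activation source localization, and dominant
    frequency / regularity-index mapping of fibrillatory rhythms.  A
    geodesic-wavefront simulator generates synthetic recordings (sinus,
    paced, focal, ablation-lesion block, ischemic slowing, fibrillatory)
    with full ground truth, so every pipeline stage is verifiable without
    animal data.  Also includes triangle-mesh readers (STL, OBJ, PLY) and
    discrete angle-deficit Gaussian-curvature analysis of epicardial
    shell geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
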