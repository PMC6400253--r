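Package: microzoo
Title: Hardware-Free Automated Crystallographic Data-Collection Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation and planning library for fully automated
    macromolecular crystallography beamline experiments. Provides a virtual
    beamline (synthetic cryoloop microscope images and raster-scan
    diffraction responses generated from ground-truth crystal
    configurations), loop centering with face-angle determination by cosine
    fitting, a peakfinder8-style diffraction spot finder with 5 Angstrom
    low-resolution scoring and heat-map assembly, crystal segmentation and
    mixed-scheme categorization (helical full rotation, partial helical,
    small wedge, clustered), serial rotation (SS-ROX) scan planning, and
    absorbed-dose budgeting that inverts a thin-crystal absorption model to
    propose exposure conditions under a megagray dose limit. An orchestrator
    drives the full mount-center-raster-plan-collect sequence per sample and
    emits machine-readable collection reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
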