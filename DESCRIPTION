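Package: evstereo
Title: Stereological Quantification of Extracellular Vesicle Structures
    in Serial Thin Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying extracellular vesicle structures
    (multi-compartmented microvesicles, multivesicular bodies and
    intraluminal vesicles) from 70-nm serial transmission electron
    microscopy sections of adherent cell cultures. Provides closed-form
    geometry for a pancake-shaped cell model and sphere-slab sectioning,
    a ground-truthed synthetic culture generator with a virtual
    microtome, band-sampling estimation of per-cell protrusion-site
    rates, an Abercrombie-type profile-count correction for
    vesicles-per-body estimates, Wilson intervals for observed
    proportions, and a grey-level histogram classifier for
    electron-lucent (MVB-like) lumens, together with an end-to-end
    simulation pipeline for validating the estimators against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
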