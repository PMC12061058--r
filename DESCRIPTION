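Package: fixtrack
Title: Quantification of Eccentric Fixation from Microperimetry and
    Registered Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify eccentric fixation in patients with central
    retinal disease. Registers en-face retinal images (OCT infrared,
    microperimetry SLO, fundus autofluorescence) into a common frame via
    landmark-based similarity or affine transforms, localizes the anatomic
    foveal center as the intersection of transfoveal scan lines, calibrates
    a per-eye pixel-to-micron ruler from the image scale bar, and computes
    fixation metrics: distance from the foveal center (DFC), distance
    between preferred retinal loci (DPRL), fixation quadrant, bivariate
    contour ellipse area (BCEA), P1/P2 percentages and fixation-stability
    class. Includes inter-grader agreement statistics (Pearson,
    Bland-Altman), a synthetic phantom and fixation-cloud generator for
    validation, open CSV/JSON interchange formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
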