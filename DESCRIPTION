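Package: rootmotion
Title: Three-Dimensional Aortic Root Motion Metrics from Surface
    Displacement Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies three-dimensional aortic root motion from a
    diastolic aortic surface mesh, a vertex-wise diastole-to-systole
    displacement field (as produced by deformable image registration of
    dynamic CT angiography), and anatomical landmarks.  Builds an analysis
    plane at the coronary-ostia level of the sinuses of Valsalva, slices
    the mesh into a lumen contour, and computes directional displacements
    (total, axial, in-plane and their relative fractions), area ratio and
    distensibility, axial tilt, aortic rotation, and the LV/Ao angle.
    Includes a parametric root phantom with analytically known
    deformations for validation, rank-based group-comparison and
    regression statistics for cohort analysis, Dice-overlap registration
    quality checks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
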