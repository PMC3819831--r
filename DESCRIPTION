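Package: regrefine
Title: Interactive Multigrid Refinement of Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for revising a coarsely registered medical image pair by
    hand-editing a hierarchy of cubic B-spline control lattices. A multilevel
    free-form deformation model (control-point spacing halved per level, the
    per-level displacement fields summed) is driven by recorded drag and
    grid-refinement events, supervised by the mean squared intensity
    difference (SSD) over the image overlap, and visualized with an RGB
    fusion overlay in which aligned structures appear gray and misaligned
    structures green or purple. Includes backward-mapping image warping with
    nearest, linear and cubic interpolation, a replayable JSON session
    format, a greedy SSD-guided auto-revision helper, a synthetic phantom
    generator with known ground-truth deformations, readers and writers for
    PNG, TIFF, NIfTI and MetaImage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    RNifti,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
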