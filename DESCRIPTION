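Package: diffusemap
Title: Construction, Quality Assessment and Motion-Model Fitting of
    Macromolecular X-Ray Diffuse Scattering Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts rotation-series x-ray diffraction frames into
    three-dimensional anisotropic diffuse scattering maps. Provides
    detector-frame preprocessing (static and statistical pixel masking,
    exposure-scaled background subtraction, polarization, solid-angle,
    detector-absorption and parallax corrections, Bragg-pixel cleaning),
    per-frame scaling with radial-profile variance removal, merging onto an
    integer-Miller voxel grid, Friedel and Laue (2/m) symmetrization, and
    isotropic-component subtraction. Map quality is scored with
    symmetry-based and reproducibility-based correlation metrics
    (CC_Friedel, CC_Laue, CC_1/2, CC_Rep, CC_Cross), and the anisotropic
    maps can be fitted with liquid-like motions (LLM) and independent
    rigid-body translation (RBT) models of correlated atomic displacements
    under zero, isotropic or anisotropic atomic displacement parameter
    treatments. A synthetic-data module generates toy atomic models,
    ground-truth diffuse volumes and complete artificial rotation series so
    the whole pipeline can be exercised without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
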