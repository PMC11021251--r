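Package: neoseg
Title: Neonatal T2-Weighted MRI Segmentation and Surface-Preparation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages for neonatal T2-weighted brain MRI
    processing: morphological refinement of over-inclusive brain masks with
    volume-preserving isotropic resampling, generation of approximate
    structure masks (cortical grey-matter ribbon, septum pellucidum,
    lateral ventricles, interhemispheric fissure, extra-cranial background
    and skull) that guide atlas registration, patch-based multi-atlas label
    fusion by similarity-weighted voting with a grey-matter-adaptive search
    radius, rule-based correction of fused labels (CSF-island reassignment,
    sulcal-bank splitting, sentinel-protected manual edits) and construction
    of the regions image consumed by deformable cortical surface extraction,
    and generation of the signed force images that modulate white-matter
    surface deformation. Includes a deterministic synthetic neonatal brain
    phantom generator with complete ground truth for validation, mm-aware 3D
    morphology, distance transforms, connected components, ridge filters and
    a 3D Canny edge detector, and a command-line driver mirroring the
    pipeline's staged directory layout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
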