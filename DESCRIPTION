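Package: spinemorph
Title: 3D Shape Descriptors and Morphology Clustering for Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes triangulated surface meshes of dendritic spines with two
    3D shape descriptors: a spherical-harmonics decomposition of the radial
    surface function (with mesh reconstruction onto a displaced icosphere) and
    a Light-Field descriptor built from Zernike moments of five orthographic
    mesh silhouettes. Includes the shared mesh preprocessing (canonical
    orientation from the dendrite-junction region, internal-center placement
    on the shape skeleton, ray-cast radial tabulation), symmetric Hausdorff
    accuracy evaluation, parameter grid search, a k-means clustering and
    control-versus-treated separability pipeline (Agresti-Caffo and
    chi-squared statistics), and a parametric generator of synthetic spine
    meshes (mushroom, thin, stubby, filopodia) and two-group populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    grDevices,
    tools,
    stats,
    utils,
    Rcpp,
    cluster,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    Rtsne,
    uwot
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
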