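Package: micropop
Title: Mapping Segmented Tract-Tracing Section Images into a Common Brain Reference Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for bringing serial histological section images of
    anterogradely labeled thalamic neuron micropopulations into a common
    3D reference space. The package consumes per-section linear anchoring
    vectors (QuickNII-dialect XML) and nonlinear marker refinements
    (VisuAlign-dialect JSON), recodes and cleans pixel-classifier output,
    maps segmented pixels into 10 micrometre atlas voxels with pixel-count
    quantification, and provides downstream analytics: dorsal cortical
    flatmap projection, laminar axon distributions, cortical coverage,
    maximum-projection subcortical views, SVG atlas overlays, and
    integration with single-neuron morphologies and bulk tract-tracing
    catalogues via medoid-radius membership and three-state overlap maps.
    A synthetic-study generator with known ground truth makes every stage
    testable without external atlas downloads.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
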