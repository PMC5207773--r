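Package: striomap
Title: Mesoscale Mapping of Excitatory Inputs to the Striatum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying anterograde-tracing projection data in the
    striatum: alignment of sectioned binary mask stacks to a template by
    center-of-mass registration, graded projection-density classification
    (dense/moderate/diffuse), pairwise and per-voxel input convergence,
    integer-valued thalamic confidence maps that localize projection origins at
    sub-injection resolution from overlapping injections, hierarchical voxel
    parcellation of the striatum by cortical input signatures, thresholded
    extraction of the cortico-thalamo-basal ganglia circuit graph, and analysis
    of optogenetically evoked EPSC traces (responder detection, kinetics,
    paired-pulse ratio, train dynamics, slow currents). A synthetic-scene
    generator with planted ground truth supports end-to-end validation without
    any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    igraph,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
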