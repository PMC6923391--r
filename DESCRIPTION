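Package: emsegkit
Title: Headless CNN-Based Segmentation Toolkit for Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for segmenting neuronal structures in serial-section
    electron microscopy volumes. Provides image-stack and label-volume I/O
    (PNG/TIFF/HDF5 with RGB-packed ids), chainable classic preprocessing filters
    including contrast-limited adaptive histogram equalization, a native 2D
    convolutional network engine (U-Net, ResNet, HighwayNet, DenseNet topologies
    with five loss functions, augmentation, patch training and tiled inference),
    a desk-scale flood-filling network for 3D instance segmentation,
    postprocessing into labeled 3D objects (binarization, 3D connected
    components, marker-based 3D watershed), foreground-restricted Rand scoring
    with split/merge limits and semantic overlap metrics, surface-mesh and
    annotation export, and synthetic EM-like volume generators for end-to-end
    testing. A thin command-line entry point orchestrates the workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    rhdf5,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
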