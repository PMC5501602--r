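Package: perfusim
Title: Perfusion Bioreactor Flow Simulation and Micro-CT Mineralization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady culture-medium flow and wall shear stress in a
    perfusion bioreactor holding a porous salt-leached scaffold disc, using a
    coupled free/porous (Stokes-Brinkman) finite-volume model on a staggered
    axisymmetric grid with a mesh-refinement convergence criterion. Processes
    time-lapsed, density-calibrated micro-CT volumes into mineralized-tissue
    masks and bone morphometry (BV, BV/TV) via Gaussian filtration, density
    thresholding and connected-component size filtering. Quantifies the link
    between simulated shear stress and mineralization by voxel-wise ROC
    analysis with the Youden (least-random) operating point. Includes
    generators for synthetic scaffold phantoms, shear-stress-driven weekly
    mineralization series and micro-CT-like acquisitions, so the full pipeline
    runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
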