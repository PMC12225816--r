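Package: spsd
Title: Stochastic Parametric Skeletal Dosimetry Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel phantoms of hematopoietic bone segments for active
    bone marrow dosimetry. Ships a curated database of 289 unique bone-segment
    parameterizations covering eight reference individuals (newborn to adult,
    both sexes): geometric primitive, linear dimensions, face-selective
    cortical thickness, and spongiosa microarchitecture (BV/TV, Tb.Th, Tb.Sp).
    Segments are rasterized on isotropic grids, spongiosa is filled with
    stochastically oriented rod-like trabeculae calibrated to the bone volume
    fraction target, and phantoms are verified by voxel morphometry
    (local-thickness Tb.Th and Tb.Sp). Includes correlated-parameter cohort
    simulation of inter-individual variability, skeleton-level roll-ups of
    media volumes and masses, active-marrow-weighted effective dose-forming
    parameters, and NRRD export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
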