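Package: lenscount
Title: Epithelial Cell Number in the Intact Mouse Lens from Orthographic
    Confocal Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the total number of epithelial cells in an intact
    mouse lens from two orthogonal confocal image stacks (anterior and
    equatorial aspects). Image stacks are collapsed to maximum-intensity
    orthographic projections; nuclei are detected by expected size and
    brightness and reduced to centroids; the two views are registered via
    constellations of EdU-positive (proliferating) nuclei; cells are counted
    in a 60-degree anterior sector and a 10-degree equatorial trapezoid and
    extrapolated azimuthally (x6 and x36) to the spherical cap and the
    equatorial band, whose sum is the total. A ground-truthed synthetic lens
    generator renders two-channel voxel stacks so every stage of the
    pipeline is verifiable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
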