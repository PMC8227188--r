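Package: foveapit
Title: Foveal Pit Morphometry from OCT Retinal Thickness Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Characterization of foveal pit morphology from optical
    coherence tomography (OCT) retinal layer segmentations: total retinal
    thickness (TRT) map construction, four foveal center location
    strategies, triangulation-based piecewise-cubic resampling of
    scattered A-scan data to regular grids and radial profiles, six
    parametric pit models plus LOESS and moving-average smoothing, pit
    geometry extraction (central foveal thickness, rim height, rim
    radius, maximum slope), and the agreement statistics used to compare
    acquisition protocols (alignment dissimilarity, fitting RMSE,
    estimation bias, ICC(2,1) with percentile bootstrap, rank-based
    distribution tests).  A synthetic raster/star OCT scan generator
    supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deldir,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
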