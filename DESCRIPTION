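Package: respace
Title: Global Receptor Nearest-Neighbor Spacing from Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates global cell-surface receptor nearest-neighbor spacings
    from calibrated immunofluorescence images. Implements a serial-dilution
    calibration fit (fluorescence to antibody count under a 1:1
    antibody-to-receptor assumption), trainable pixel classification of cell
    versus background, allocation of the calibrated receptor total over cell
    pixels proportional to intensity with a random-sequential-adsorption
    jamming cap, conversion of per-pixel density to within-pixel
    nearest-neighbor spacing, spacing distributions and percentile-capped
    heatmaps. Also provides a multi-channel selectivity pipeline for
    spatially constrained bivalent ligands (Z-projection, mask-based signal
    quantification, background filtering, global normalization, condition
    statistics), geometric design of bivalent DNA Y-scaffold ligand spacings
    with a persistence-length rigidity check, and a seeded synthetic-image
    generator (Poisson and Thomas receptor fields, Gaussian PSF, Poisson shot
    plus Gaussian read noise, calibration series, three-channel Z-stacks with
    spacing-dependent bivalent binding) so the whole analysis is testable
    end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    randomForest,
    jsonlite,
    tiff,
    png,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
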