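Package: ocmheart
Title: Quantification of Drosophila Heart Function from M-Mode Optical Coherence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cardiac structure and function of the Drosophila
    heart from M-mode optical coherence microscopy (OCM) recordings. Implements
    seeded region-growing (magic-wand) segmentation of the heart-chamber lumen,
    beat detection on the chamber-area trace, heart rate and end-diastolic /
    end-systolic dimensions and areas, fractional shortening, the cardiac
    activity period (CAP) duty-cycle statistic, cardiac developmental diastasis
    (CDD) duration across pupal development, and genotype group comparisons.
    Includes a synthetic M-mode phantom generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    zoo,
    withr,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
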