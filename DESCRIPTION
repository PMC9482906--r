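Package: steroquant
Title: Parallel Targeted and Untargeted Steroid Quantitation for LC-HRMS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute steroid quantitation from liquid
    chromatography high-resolution mass spectrometry (LC-HRMS) data.
    Implements the parallel targeted / untargeted workflow: extracted-ion
    chromatogram (XIC) extraction at fixed absolute m/z tolerance, peak
    integration, internal-standard-normalised calibration with weighted
    least squares, surrogate calibration of untargeted steroids via
    compound-specific ionization-efficiency correction factors, an FDA-style
    bioanalytical validation battery (accuracy, precision, carryover, LLOQ
    determination, stability), apparent steroidogenic enzyme activities as
    product-to-substrate ratios, composite menstrual-cycle-phase
    classifiers, Spearman correlation clustering by steroid class and
    matrix, and a synthetic-data generator with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
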