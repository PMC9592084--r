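Package: flimion
Title: Fluorescence-Lifetime Photometry and Ion-Pump Modeling for Neuronal
    Glycolysis Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon fluorescence-lifetime (FLIM)
    photometry of genetically encoded biosensors in brain slices: simulation
    and maximum-likelihood fitting of time-correlated single-photon counting
    (TCSPC) histograms with a Gaussian instrument response ("tau8" lifetimes),
    red/green spectral bleed-through unmixing, quantification of
    stimulus-evoked biosensor transients (delta-F/F, peak, half-decay,
    exclusion rules, cohort averaging and normality-gated group comparisons),
    SBFI dye calibration between delta-F/F and intracellular sodium, and a
    Hill model of Na+/K+-pump activation with Na+/Ca2+-exchanger transport
    stoichiometry.  Includes a mechanistic synthetic-experiment generator
    (stimulus-evoked Ca2+, Na+ and NADH transients rendered as sensor traces
    and photon-level TCSPC histograms) so the full pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
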