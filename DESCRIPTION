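Package: msgmm
Title: Whole-Spectrum Gaussian Mixture Modeling of Proteomic Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated Gaussian mixture modeling of profile-mode proteomic
    mass spectra (MALDI-ToF and similar). The spectrum is partitioned into
    fragments anchored at high-quality "clear" peaks: a mixture model is
    fitted around each such peak, its reliable central components (the
    "splitter") are subtracted from the signal, and the residual segments
    between splitters are decomposed independently by an EM algorithm for
    binned count data. Component sets are aggregated into a whole-spectrum
    model. Includes weight filtering and component merging for peak
    extraction, a higher-narrower component estimator for skewed peaks,
    detection metrics (FDR, sensitivity, F1, relative error), and a
    virtual-mass-spectrometer style simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    mclust,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
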