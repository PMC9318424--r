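Package: synergydecoder
Title: Synergy-Based Neural Decoding of Hand Grasp Kinematics from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting low-dimensional kinematic synergies from
    multi-joint hand grasp recordings by singular value decomposition, for
    turning multi-channel EEG into windowed spectral-power features, and for
    decoding held-out subjects' hand kinematics from their EEG alone through
    cross-subject multivariate linear regression. Includes a synthetic cohort
    generator with known ground-truth synergy structure and a linear band-power
    encoding of synergy weights, decoding-accuracy scoring (Pearson correlation
    and 1 - |rho| error), and electrode-neighborhood regression maps of the
    cortical involvement of each synergy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
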