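Package: pureshiftr
Title: Simulation and Analysis of Real-Time Pure Shift 15N HSQC NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-matrix simulation toolkit for real-time pure shift
    proton-detected 15N HSQC NMR of proteins.  Builds small amide spin
    systems, propagates them through chunked-acquisition homodecoupling
    schemes (BIRD and band-selective BASHD J-refocusing elements, with or
    without coherence-transfer-pathway gradient selection), models
    residual water with radiation damping, and processes the resulting
    chunked free induction decays into 1D and 2D spectra.  Includes
    selective-pulse (reBURP) synthesis and calibration, decoupling
    sideband and signal-to-noise quantification, and closed-form
    sensitivity rules for multiplet collapse, element-duration losses and
    time-shared duty-cycle penalties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
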