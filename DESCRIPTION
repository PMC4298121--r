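Package: vascmr
Title: Site-Specific Vascular Markers from Cardiovascular Magnetic Resonance
Version: 0.1.0
Authors@R:
    person("Vascular", "Imaging Lab", email = "vascmr@example.org", role = c("aut", "cre"))
Description: Tools for site-specific analysis of vascular disease markers
    derived from cardiovascular magnetic resonance: transit-time aortic pulse
    wave velocity from velocity-encoded flow curves, carotid normalized wall
    index from inner/outer vessel-wall contours, 27-segment peripheral
    stenosis scoring (Mean SC / Max SC), and a cohort association analysis
    with cell-wise outlier handling, pairwise-complete correlations and
    multiple linear regression with standardized coefficients. Ships a
    calibrated latent-variable synthetic cohort generator with known ground
    truth for end-to-end validation of the measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
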