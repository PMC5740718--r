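Package: twinewas
Title: Discordant Monozygotic Twin EWAS of Lung Function
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association analysis pipeline for discordant
    monozygotic twin designs applied to lung function. Provides LMS-based
    spirometry z-score standardization, intra-pair difference construction
    (superior minus inferior twin), 450K-style methylation probe quality
    control, beta/M-value transforms, reference-based blood cell
    deconvolution, genome-wide pair-difference linear regression with
    Benjamini-Hochberg false-discovery-rate control, and hypergeometric
    over-representation pathway analysis against the array gene universe.
    Includes a synthetic twin-cohort generator with planted probe-level
    effects so that every stage is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
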