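Package: dermivivc
Title: In Vitro-In Vivo Correlation for Topical Drug Products from
    Release Testing and Tape Stripping
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to establish a Level C in vitro-in vivo correlation
    (IVIVC) for topical semisolid drug products. Computes
    withdrawal-corrected cumulative release and Higuchi apparent release
    constants (ARC) from vertical-diffusion-cell in vitro release testing
    (IVRT), turns tape-stripping records into drug-amount versus relative
    stratum corneum depth profiles and trapezoidal AUCs using TEWL-derived
    stratum corneum thickness, fits the linear ARC-AUC correlation,
    and derives bioequivalence acceptance windows (0.80-1.25) for both
    parameters. Includes a synthetic-data generator with the statistical
    structure the analysis assumes, so the full pipeline is testable by
    parameter recovery, and a command-line pipeline with CSV input/output
    and reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
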