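Package: sclerafit
Title: Poroelastic Characterization of Scleral Compression Tests and
    Ocular Biometry Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying scleral tissue biomechanics from
    unconfined-compression stress-relaxation experiments using a biphasic
    (poroelastic) model with tension-compression nonlinearity, together with
    the statistical layer used in rodent myopia studies: longitudinal ocular
    biometry shift and change-from-baseline statistics, gamma log-link group
    contrasts with strain or timepoint interactions and multivariate-t
    multiplicity adjustment, spectrophotometric assay quantification, and
    seeded synthetic-data generators so every stage of the pipeline can be
    exercised and validated without access to raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
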