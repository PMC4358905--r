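Package: qsarkit
Title: QSAR Model Life-Cycle Toolkit with PLS, FFD Selection and
    Applicability-Domain Assessment
Version: 0.1.0
Authors@R:
    person("QSAR", "Toolkit Developers", email = "qsarkit@example.org",
           role = c("aut", "cre"))
Description: Builds, validates, versions and deploys quantitative
    structure-activity relationship (QSAR) models from SDF (MDL V2000)
    training series. Provides an in-house NIPALS partial least squares
    engine (regression and discriminant modes) with leave-one-out
    cross-validation, fractional-factorial-design (FFD) variable
    selection, a six-criterion applicability-domain reliability
    assessment, a versioned on-disk model store with sequential
    publication and forensic reproducibility, and a confidential
    coefficient-only model export that retains no per-compound
    information. Includes a command-line interface and deterministic
    synthetic-fixture generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
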