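Package: protrace
Title: Fecal Protease Activity Profiling from Kinetic Fluorescence Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-substrate, multi-pH fluorogenic (AMC) protease
    activity assays run on microplate readers, from raw kinetic fluorescence
    traces to cohort-level enzymatic signatures. Provides plate normalization
    against empty-well references, intrinsic-fluorescence quality control and
    background subtraction, deterministic linear-phase detection with
    ordinary-least-squares rate estimation in RFU/min, replicate aggregation,
    sample-by-(substrate, pH) activity matrices, normalized substrate- and
    protease-class-level contribution profiles, group comparisons (pooled and
    paired t tests), ROC/AUC discrimination, inhibitor (percent-of-control)
    quantification, and a synthetic plate-reader data generator with ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
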