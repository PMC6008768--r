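Package: petpbpk
Title: Whole-Body PBPK Modelling of Dynamic Mouse PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) analysis of dynamic
    whole-body PET data in mice. Implements a nine-compartment mass-transfer
    model (plasma, two hepatic, gallbladder/intestine, two renal, two
    peripheral-tissue compartments and urine) with short-infusion input,
    a closed-form two-compartment infusion model for plasma kinetics,
    weighted multistart bounded least-squares fitting of regional
    time-activity curves, derivation of hepatobiliary and renal clearances,
    hepatic extraction ratio and tissue distribution coefficient from the
    fitted rate constants, group comparison by pooled-variance t-tests, and
    a synthetic-scan generator for end-to-end validation without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'physiology.R'
    'scan.R'
    'preprocess.R'
    'plasma_model.R'
    'pbpk_model.R'
    'fit_engine.R'
    'derived_pk.R'
    'synthetic.R'
    'pipeline.R'
    'petpbpk-package.R'
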