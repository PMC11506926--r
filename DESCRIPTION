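Package: piperpbpk
Title: Physiologically Based Pharmacokinetics of Piperine and
    CYP3A4-Mediated Food-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open pipeline for mechanistic pharmacokinetic modeling of
    dietary piperine as a time-dependent CYP3A4 inactivator.  Estimates
    intrinsic clearance from microsomal substrate-depletion time courses,
    predicts steady-state volume of distribution by the Rodgers-Rowland
    mechanistic tissue-composition method, scales in vitro clearance to
    whole-organ clearance (IVIVE, well-stirred liver), simulates oral
    dosing with a reduced gut-liver-systemic PBPK model coupled to
    CYP3A4 enzyme-turnover dynamics, and predicts victim-drug AUC and
    Cmax ratios for co-administration with repeated piperine intake,
    including virtual-trial between-subject variability and two-fold
    fold-error model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
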