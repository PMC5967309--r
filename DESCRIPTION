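Package: copdcid
Title: Composite Clinically Important Deterioration Endpoints in COPD Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and analysis of the composite clinically important
    deterioration (CID) endpoint used in pooled COPD bronchodilator trials:
    per-patient classification of longitudinal visit records into first and
    sustained CID events (>=100 mL pre-dose FEV1 drop, >=4 point SGRQ rise,
    or a moderate-to-severe exacerbation), time-to-event analysis
    (Kaplan-Meier, log-rank, stratified Cox proportional hazards), subgroup
    forest tables and at-event summaries, plus a calibrated synthetic
    pooled-trial generator so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
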