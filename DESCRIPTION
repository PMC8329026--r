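Package: dyadload
Title: Collaboration-Load Metrics from Pupillary and Gaze Responses in Dyadic Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and analysis chain for quantifying collaboration load in
    task-oriented dyadic interaction. Cleans binocular pupil-diameter streams
    (binocular merge, gap interpolation, zero-phase low-pass Butterworth filtering,
    range and z-score outlier exclusion, baseline referencing) and extracts
    per-utterance task-evoked pupillary response metrics (mean dilation, peak
    dilation, slope). Assigns per-frame 3D gaze targets by visual angle and computes
    attention measures (first gaze to target referent, proportional gaze to
    target/other/person, joint attention, mutual gaze). Codes annotated utterance
    tiers into fragmented and non-fragmented instruction units with fragment
    ordinals, fits linear mixed models with likelihood-ratio chi-square tests for
    fragmentation, role and their interaction, and screens Spearman correlations
    with Bonferroni correction. A synthetic dyad generator with scripted ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
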