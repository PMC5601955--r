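Package: emgmpr
Title: Myoelectric Pattern Recognition for Non-Weight-Bearing Lower-Limb EMG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for real-time myoelectric
    pattern recognition (MPR) of non-weight-bearing lower-limb movements from
    multichannel surface electromyography (sEMG). Provides a synthetic session
    generator emulating a 16-channel, 2 kHz recording protocol with an
    amplifier front-end model; signal treatment (contraction trimming,
    concatenation, overlapping-window segmentation); classic time-domain
    feature extraction (mean absolute value, waveform length, slope sign
    changes, zero crossings); linear discriminant analysis in a one-vs-one
    topology with majority voting; a streaming Motion Test simulator with the
    four standard real-time metrics and cumulative completion curves; exact
    nonparametric configuration-comparison statistics (Wilcoxon signed-rank
    and rank-sum with Bonferroni correction); and phantom-limb-pain outcome
    scoring (numeric rating scale, SF-MPQ pain rating index, weighted pain
    distribution) with longitudinal change summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
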