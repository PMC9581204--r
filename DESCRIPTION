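Package: isostiff
Title: Sigmoid Isostiffness Modelling of Aortic Valve Area Flow Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the flow dependence of the aortic valve
    opening area (AVA) in pulsatile flow-loop experiments. Provides a
    waveform-level synthetic data generator for a left-heart simulator
    (pump position, transvalvular flow with a retrograde notch, ventricular
    and aortic pressures, and a high-speed-camera valve-area series),
    signal-processing utilities (circular cross-correlation delay
    estimation, moving-average smoothing and decimation, ejection-window
    detection, peak-flow point extraction), beat-level hemodynamic
    summaries (cumulative left-ventricular work, mean systolic flow, mean
    transvalvular gradient, work-ratio relative stiffness), linear and
    saturating sigmoid AVA-flow models fitted by Levenberg-Marquardt least
    squares in a modified leave-one-valve-out cross-validation, projection
    of AVA from low-flow to high-flow states, agreement statistics
    (Bland-Altman, AIC-based model comparison), and isostiffness-line
    nomograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
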