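Package: svsdg
Title: Directional Brain-Heart Interplay from Heartbeat and EEG Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of time-resolved cardiac sympathetic and
    parasympathetic activity indices from RR-interval series via Laguerre
    expansions and Kalman filtering, and of bidirectional (brain-to-heart
    and heart-to-brain) coupling coefficients between those autonomic
    indices and EEG band power, following the sympathovagal synthetic
    data generation (SV-SDG) framework.  Includes EEG band-power
    extraction (Butterworth filtering, short-time Fourier transform,
    band integration), minimum-redundancy-maximum-relevance feature
    ranking, condition-wise nonparametric statistics, cross-validated
    kernel regression and kernel naive Bayes classification of graded
    mental stress, and a forward simulator of protocol-structured
    datasets with known ground-truth couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
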