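Package: mpspindle
Title: Matching Pursuit Parametrization and Detection of EEG Transients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Time-frequency parametrization of transient EEG activity by
    matching pursuit decomposition over a Gabor dictionary whose density is
    governed by a single energy-error parameter.  Fitted atoms are turned
    into detections of sleep spindles, slow waves and other transients by
    explicit criteria on frequency, duration and amplitude, with the minimal
    spindle amplitude derived from a percentile of the sigma-band windowed
    RMS distribution.  Includes sample-resolution detector evaluation
    (sensitivity, PPV, Matthews correlation, Cohen's kappa, F1),
    cross-validated percentile selection, per-epoch EEG profiles, a
    synthetic-EEG generator with ground-truth annotations, and minimal
    EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
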