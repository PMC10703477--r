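Package: motionkit
Title: Kinematic, Gait and Biosignal Analysis of Tracked Motion Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing tracked point-of-interest coordinates from
    video tracking and pose estimation together with electrophysiology and
    sensor traces. Provides readers for column-wise coordinate and signal
    tables (CSV/TSV/TXT, spreadsheets, DeepLabCut output), trajectory
    preprocessing (outlier replacement, smoothing, affine alignment,
    multi-camera stitching), kinematic quantities by forward differencing,
    joint angles, occupancy heatmaps, stick diagrams, gait-cycle
    decomposition into stance and swing phases with stride and step
    parameters, EMG-style rectification and envelopes, Butterworth
    filtering, power spectra and spectrograms, auto- and cross-correlation,
    FFT phase-lag and amplitude-ratio estimation, band-constrained dynamic
    time warping, deterministic synthetic validation fixtures, file-based
    plotting, and a lossless session archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    signal,
    pracma,
    jsonlite,
    yaml,
    zip
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
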