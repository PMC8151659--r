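Package: vrgait
Title: Gait Event Detection and Spatiotemporal Stride Analysis from VR Foot Trackers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for computing spatiotemporal gait parameters from
    consumer virtual-reality foot trackers. Reads timestamped 3D pose logs
    (position plus unit quaternion) from instep-mounted trackers, applies
    zero-phase low-pass Butterworth filtering and linear detrending, maps
    tracker pose to heel position through a rigid shoe-frame offset,
    detects toe-off and heel-strike events from the double-peaked vertical
    foot-clearance waveform, segments gait cycles, and computes stride
    length, stride time, stride width, stride velocity and stance/swing
    percentages. A validation layer scores detected events and features
    against a reference event stream (instrumented-walkway style) via
    tolerance-window one-to-one matching, sensitivity, median-absolute-
    deviation outlier rejection, offset statistics, RMSE, Pearson
    correlation and Bland-Altman limits of agreement. A synthetic gait
    simulator generates paired tracker and reference streams with known
    ground truth so the full pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
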