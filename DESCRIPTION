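Package: neuroloop
Title: Closed-Loop Simulation of a Robot-Embodied Neuronal Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop neurorobotic ("embodied network") system in
    which a hue-thresholded camera image of a moving target drives stimulation of
    a two-hemisphere multi-electrode-array (MEA) neuronal network, network spiking
    is decoded through a leaky activation vector matched against left/right
    templates, and the resulting motion commands steer a one-dimensional robot
    arm that carries the camera. Provides the synthetic scene generator, the
    five-strip vision pipeline with 500-pixel stimulation quanta, an
    inhomogeneous-Poisson 60-channel network simulator with hemisphere-confined
    evoked responses, threshold-crossing spike detection, exponential-decay
    activation decoding with Euclidean template classification, arm kinematics
    with return-to-midpoint homing, and tracking-accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
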