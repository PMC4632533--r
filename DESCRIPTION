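Package: segbody
Title: Segment-Based Musculoskeletal Modelling of the Lower Limb
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates lower-limb muscle, ligament and joint contact forces
    from motion-capture marker trajectories and ground reaction forces by
    posing fully segment-based, simultaneous equations of motion for the
    foot, shank and thigh and resolving the muscle redundancy with per-frame
    constrained minimisation of a cubic load-sharing cost. Includes a
    regression model of patellar posture and the patellar/quadriceps tendon
    force ratio, muscle-path via points and cylinder wrapping, anthropometry
    scaling, Geers' magnitude/phase curve-comparison metrics, and a generator
    of dynamically consistent synthetic jump trials for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
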