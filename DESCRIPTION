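Package: trajkin
Title: Trajectory-Shape Kinematics for Markerless Upper-Limb Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional assessment of upper-limb motion recorded
    with low-cost markerless (depth-camera) skeleton trackers. Reads and
    validates 3D skeleton streams, builds segment local coordinate systems
    with root-outward link-length correction, extracts child-in-parent
    relative joint trajectories, and computes 41 trajectory-shape descriptors
    per trajectory: hodograph travel, swept angle and velocity statistics,
    inertia-based principal axes with rhomboid/diamond reach measures,
    least-squares sphere fits, and convex-hull surface, conic volume and
    solid-angle workspace metrics. Patient trials are summarised as
    dimensionless weighted scores against a reference group with star-plot
    export, device-agreement (Pearson R, reproducibility coefficient,
    coefficient of variation) and group-comparison (one-way ANOVA with
    Bonferroni post hoc) statistics, plus a seeded generator of
    Kinect-like synthetic wiping-exercise cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    minpack.lm
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
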