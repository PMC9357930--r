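Package: boxkin
Title: Upper-Limb Kinematics by Multibody Kinematic Optimization and
    Method-Agreement Analysis for Boxing Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare marker-based and markerless estimates of
    upper-extremity kinematics in highly dynamic movements such as boxing.
    Implements a constrained upper-body multibody model (thorax root,
    clavicle, upper arm, forearm and hand per side), weighted multibody
    kinematic optimization of generalized coordinates against labeled
    marker trajectories, extraction of cardan joint angles, joint-center
    trajectories and segment center-of-mass speeds with zero-phase
    Butterworth filtering, and a Bland-Altman agreement battery (bias,
    confidence interval with normality branching, R squared, RMSD, and
    median/IQR joint-center distances). A synthetic-data module generates
    punch-like ground-truth motion, soft-tissue-artifact-corrupted marker
    data and an emulated markerless pose stream so the whole chain can be
    validated end to end without laboratory data. Includes TRC, C3D and
    CSV pose-stream readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
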