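Package: batroll
Title: Developmental Model of Sonar Localization with Active Head Rolls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop simulator of developmental sonar-based sound
    localization in the big brown bat. An agent concurrently learns a
    binaural auditory representation (a bank of generative adaptive
    subspace self-organizing maps) and a head yaw/pitch control policy
    (natural actor-critic) while random head rolls drawn from an
    autoregressive process tilt the interaural axis. Includes Fick-gimbal
    head kinematics with Listing torsion, a synthetic head-related
    transfer function generator with binaural echo rendering, a cochlear
    front-end variant, and an analysis battery: step-response time
    constants, steady-state localization error, reconstruction-error
    surfaces, basis-vector cue characterization, pure-tone tuning-curve
    classification and distribution comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
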