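Package: merdbs
Title: Predicting Deep Brain Stimulation Motor Outcome from Microelectrode
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for predicting the motor
    response class after bilateral subthalamic deep brain stimulation (DBS)
    from intraoperative microelectrode recordings (MER). Raw extracellular
    waveforms are converted to Morlet continuous-wavelet-transform scalogram
    images in three frequency bands (1-50, 50-500, 500-5000 Hz) and
    classified by a VGG-style convolutional network with a shared trunk and
    two task-specific heads, trained jointly against the contralateral and
    ipsilateral UPDRS part III DBS on/off outcome with an asymmetric
    weighted cross-entropy loss. A synthetic cohort generator with
    controllable band-specific signal content and bilaterally correlated
    outcomes makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
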