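Package: semgsim
Title: Fiber-Level Simulation of Surface Electromyography and Muscle Force
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates surface electromyography (sEMG) and muscle force from a
    desired force-time profile, taking the single muscle fiber as the basic
    unit of activation. A motor-control stage recruits motor units under the
    Henneman size principle against a cumulative force-response table; motor
    neurons release acetylcholine profiles that trigger fiber innervation by
    threshold; innervated fibers propagate balanced tripole current sources
    along 3D fiber paths (Rosenfalck membrane model) and produce twitch forces
    that sum over impulses; a voxel finite-element volume conductor maps each
    traveling pole to voltages at skin electrodes, yielding monopolar and
    bipolar sEMG channels together with the total contraction force. Includes
    a layered cylindrical arm phantom, reference force-profile generators,
    and signal-similarity metrics (RMS, median frequency, envelope
    correlations, general similarity index) for validating simulated signals
    against recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    Matrix,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
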