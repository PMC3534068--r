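Package: crowdmotion
Title: Bio-Inspired Cortical Motion Analysis of Crowd Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A model of visual motion processing in the primate dorsal stream
    (areas V1, MT and MSTd) applied to the analysis of crowd videos. Detects
    initial motion with a phase-based extended Hassenstein-Reichardt
    correlator over a Gabor filter bank, integrates motion in a velocity-space
    population code with divisive normalization and soft center-surround
    competition so that motion transparency (multiple motions at one location)
    can be represented, matches global optic-flow patterns (expansion,
    contraction, rotation and spirals) with MSTd-like templates, and reads the
    representation out into no/single/multiple motion class maps, velocity
    fields, velocity-gradient maps and danger-zone maps. Includes seeded
    generators for random-dot, lane and flow-pattern stimuli and a
    social-force pedestrian simulator so the full pipeline can be exercised
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
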