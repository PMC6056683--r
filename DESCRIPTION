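Package: bcloop
Title: Hybrid Passive-BCI Biocybernetic Loop for Adaptive Game Difficulty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A closed-loop control toolkit for hybrid passive brain-computer
    interfaces. An EEG pipeline turns raw multichannel recordings into a
    normalized upper-alpha (10.5-13 Hz) power ratio at 2 Hz, with
    Riemannian-distance artifact rejection; dual-threshold controllers map the
    ratio onto game-difficulty adaptations of a headless Tetris engine; a
    secondary facial-expression valence signal continuously re-tunes the
    thresholds (dynamic thresholding). A simulated subject (placement policy
    plus generative alpha and valence models) closes the loop so every
    controller is runnable and testable offline, and session metrics summarise
    the behaviour of each condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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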