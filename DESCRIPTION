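Package: chordscene
Title: Prototype-Based Scene Encoding and Similarity-Preserving Associative Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing shapes and two-object scene layouts by their
    distances to a fixed set of prototypes (the chorus transform), for rank-order
    and locality-sensitive hashing over such codes, and for a content-addressable
    scene memory in which each scene is stored redundantly under each of its
    regions of interest.  Includes a seeded synthetic scene generator (parametric
    grayscale object families composed into 150 x 150 scenes) and reproducible
    runners for three simulation experiments: productivity under novel scene
    constituents, graded dissimilarity under progressive object displacement, and
    sensitivity to qualitative structural change (translation versus reversal).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
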