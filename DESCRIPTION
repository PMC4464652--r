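Package: vosim
Title: Recurrent Connectionist Simulation of Verbal Overshadowing in Face Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a fully interactive recurrent network model of face
    recognition, verbalization and mental imagery, trained by backpropagation
    through time on a factorial set of 64 synthetic binary face images. Provides
    the stimulus generator (binary face images, Gaussian-degraded retinotopic
    inputs, localist verbal feature labels), the activation dynamics with soft
    and hard clamping of external inputs, the training curriculum (visual
    pre-training followed by interleaved three-task training), entropy-based
    polarity (familiarity) scoring with criterion-based old/new recognition
    judgments, multidimensional scaling of hidden-layer trajectories, and a
    harness for verbalization experiments that reproduce verbal overshadowing
    under the recoding-interference account, including similar/dissimilar
    distractor conditions, irrelevant-face verbalization, graded verbal
    description accuracy, and single-trial lineup testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
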