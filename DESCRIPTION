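Package: dotmatch
Title: Scoring and Simulation of Dot-Annotation Cell Competitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation machinery for crowdsourced dot annotations of cells
    in Ki67-stained breast cancer image tiles. Implements radius-limited
    one-to-one matching of point annotations against pathologist ground
    truth, competition accuracy, per-class precision/recall/F1 and confusion
    matrices, level gating and leaderboards, a seeded generative model of
    annotator behaviour (misses, localisation jitter, class confusion,
    spurious dots) with parameter recovery, a stylised IHC tile renderer,
    and a small-data patch-classifier comparison of frozen-feature versus
    end-to-end training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    nnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
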