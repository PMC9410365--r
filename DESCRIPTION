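Package: finclass
Title: Flat and Hierarchical Fish Species Classification from Underwater Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying fish species in unconstrained underwater
    imagery with two complementary strategies: (1) flat transfer-learning
    classification with a pluggable feature trunk, a freshly trained softmax
    head, and targeted data augmentation driven by per-class train/validation
    loss-curve divergence; and (2) taxonomy-driven hierarchical classification
    with a shared trunk, a family-level root node, per-family species leaf
    nodes (optionally extended with an 'Others' rejection class for confusable
    families), staged training, and greedy test-time routing. Includes
    stratified split protocols, macro-precision / micro-accuracy evaluation,
    and a synthetic taxonomy-structured image generator so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
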