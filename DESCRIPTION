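Package: narcnn
Title: Network Auto-Reduction of Convolutional Neural Networks for
    Histopathology Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compound simplification of block-based convolutional neural
    networks for digital pathology. Implements Network Auto-Reduction (NAR),
    which shrinks the depth, width and input resolution of a network together
    through coupled scaling coefficients, alongside an input-reduction
    baseline that shrinks only the image. Ships a framework-neutral
    intermediate representation of block-based architectures with built-in
    ResNet50 V2 and Inception V4 templates, an analytic FLOPs and parameter
    cost model with full shape inference, a pure-R trainable runtime with
    Adam optimisation, a patch-classification pipeline that tiles slide
    images into fixed physical-size patches and renders tumor-infiltrating
    lymphocyte maps, and a deterministic synthetic-fixture generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
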