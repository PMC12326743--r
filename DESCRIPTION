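Package: protofed
Title: Federated Few-Shot Classification of Volumetric Knee MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Episodic few-shot diagnosis of knee MRI findings with
    Prototypical Networks over a trainable 3D convolutional embedding
    backbone, plus a simulated two-stage horizontal federated protocol
    (local episodic training, size-weighted model averaging, local
    fine-tuning on disjoint classes). Includes MRNet-layout dataset I/O
    with label-powerset encoding of the abnormality/ACL/meniscus label
    triples, volume preprocessing (slice-count standardization by weighted
    interpolation, intensity normalization, channel replication, training
    augmentation), an episodic evaluation harness (confusion matrices,
    macro precision/recall/F1, ROC-AUC), and a synthetic MRNet-layout
    generator with controllable class-conditional signal so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
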