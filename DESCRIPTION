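Package: bihada
Title: Bi-Hemispheric Adversarial Domain Adaptation for EEG Emotion
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cross-subject and cross-session EEG emotion recognition via
    adversarial domain adaptation with a class-informed (C+1) domain
    discriminator and independent left/right hemisphere branches fused by
    discriminator-derived perplexity weights.  Includes differential-entropy
    feature extraction from raw EEG, per-subject/per-session normalization,
    leave-one-subject-out and cross-session evaluation protocols with
    Holm-Bonferroni-corrected paired tests, and a synthetic feature
    generator emulating per-subject domain shift, class-conditional
    multimodal structure, and lateralized class separability so the whole
    pipeline is testable without licensed EEG datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
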