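Package: lungformer
Title: Multi-Slice Vision Transformer Classification and Radiology Report
    Generation for Lung CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable multi-slice transformer framework for three-class
    lung CT classification (Normal, SCLC, NSCLC) and bilingual radiology report
    generation. Five axial slices per patient are encoded with a ViT-Base/16
    encoder, aggregated across slices by Learnable Query Attention Pooling
    (LQAP) into a fixed 197-token patient-level context, classified through a
    patient-level attention pool, and decoded into free-text reports by a
    GPT-2-style cross-attention decoder. Includes lung-window CT preprocessing,
    a seeded synthetic cohort generator for end-to-end testing, joint
    classification/language-model training with Adam and a one-cycle schedule,
    slice-wise Grad-CAM saliency with quantitative localization metrics
    (IoU, Dice, Pointing Game), and a full classification and caption
    evaluation suite (BLEU-n, ROUGE-L, METEOR, CIDEr). All transformer
    forward and backward passes are implemented in base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
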