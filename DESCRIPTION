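Package: pcgvit
Title: Two-Stream Vision Transformer with Attention Fusion for Heart Sound Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies phonocardiogram (heart sound) recordings as normal or
    abnormal (or murmur present / absent / unknown) with a two-stream Vision
    Transformer built from scratch in R. Recordings are converted to 64x64x3
    MFCC / delta / double-delta feature images; two transformer encoder
    branches operating at 4x4 and 8x8 patch granularity are merged by a
    trainable attention fusion block, and a small fully connected head yields
    class probabilities. Includes the full training protocol (Adam, early
    stopping, subject-wise cross-validation), a fusion-strategy ablation
    harness, the evaluation metric suite including class-weighted accuracy,
    a synthetic phonocardiogram generator for end-to-end testing, and loaders
    for PhysioNet 2016/2022 style datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
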