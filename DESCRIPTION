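Package: strainspeech
Title: Optical Strain-Map Silent-Speech Decoding Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding stack for camera-based optical strain
    sensing of silent speech. Renders micromarker substrates under known
    deformations, detects markers (CLAHE, unsharp masking, Otsu
    binarization, size-filtered connected components), tracks markers of
    interest, fits homographies by RANSAC to build multiaxial strain
    amplitude/direction maps and residual-stress baseline maps, conditions
    utterance-level strain time series (smoothing, center padding,
    z-scoring, stochastic augmentation, energy-based voice activity
    detection), and classifies 26-word vocabularies with a hybrid
    CNN-Transformer including knowledge distillation and low-rank (LoRA)
    user adaptation. Includes dynamic-time-warping analytics and an
    end-to-end pipeline driver, exercised entirely on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
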