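Package: eegpatch
Title: Patch-Based Transformer Models for Multichannel EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a channel-flexible, patch-based Transformer classifier for
    multichannel EEG trials, such as motor-imagery brain-computer-interface
    recordings. EEG trials are tokenized channel-wise into fixed-length
    patches, linearly embedded, tagged with learned per-(sensor, time-slot)
    positional embeddings, and processed by a pre-layer-norm Transformer
    encoder read out through a classification token. Includes standard EEG
    preprocessing (zero-phase IIR bandpass, resampling, session-wise channel
    z-scoring), per-trial data augmentation (Gaussian noise, DC shifts,
    amplitude scaling, random time-shift cropping, channel subsampling),
    masked-patch self-supervised pre-training with a cosine reconstruction
    loss, supervised pre-training across heterogeneous montages with label
    amalgamation and weight transfer for fine-tuning, interpretability
    operators (embedding filter spectra, positional-embedding similarity,
    attention rollout), and a synthetic motor-imagery EEG generator so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
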