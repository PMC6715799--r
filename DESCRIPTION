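Package: whalecoda
Title: Sperm Whale Click Detection and Coda Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Passive-acoustic analysis of sperm whale (Physeter macrocephalus)
    vocalizations. Provides a time-domain echolocation click detector
    (zero-phase Butterworth bandpass, amplitude-threshold peak picking with
    minimum-separation suppression), automatic construction of labelled
    Tukey-window spectrogram datasets, and a small convolutional
    click/no-click classifier. Inter-click-interval (ICI) coda sequences are
    modelled with recurrent networks (LSTM and GRU) pretrained on a
    self-supervised final-interval prediction task and transfer-learned to
    classify coda type, vocal clan membership, and individual whale identity.
    Hidden features can be embedded with PCA and t-SNE for cluster
    inspection, and a synthetic coda and click-audio generator makes every
    stage of the pipeline testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    cluster,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
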