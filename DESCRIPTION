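Package: mealvoice
Title: Simultaneous Speech and Eating-Sound Recognition from Skin-Contact Microphone Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising speech and eating-behaviour events (chewing,
    swallowing) in the same audio stream, as recorded by skin-contact (throat)
    microphones. Implements the full pipeline: WAV ingestion with high-pass
    filtering, resampling and channel summation; strong (timed) and weak
    (order-only) event labels; acoustic augmentation (speed, time and frequency
    dropout) and label-initiated segmentation of long recordings; generation of
    a fixed-length synthetic corpus mixing speech and eating sounds with white
    noise padding; a frame-level acoustic model (pluggable encoder plus a
    fully connected head) trained with a Connectionist Temporal Classification
    (CTC) objective written from scratch, including best-path and prefix
    beam-search decoding; two-stage fine-tuning protocols with per-group
    optimisers and learning-rate annealing; and event-level evaluation with
    per-class temporal allowances plus character error rate for transcripts.
    A synthetic toy-audio world lets every stage run end-to-end on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
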