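Package: speechFFR
Title: Temporal Response Functions for the Cortical Speech
    Frequency-Following Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and statistical analysis of the cortical
    contribution to the speech frequency-following response (speech-FFR)
    from continuous neural recordings.  Extracts two fundamental-frequency
    band speech features (the fundamental waveform and the envelope
    modulation of the higher harmonics), estimates temporal response
    functions (TRFs) by lagged ridge regression, assesses their
    significance against time-reversed noise models by bootstrap, and
    quantifies attentional modulation and its relation to musical
    training at the cohort level.  A synthetic-data generator produces
    stimuli, neural responses with known ground-truth kernels, and
    cohorts, so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
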