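Package: peakyspeech
Title: Peaky Speech Stimuli and Subcortical Responses to Continuous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Re-synthesizes continuous speech so that the phases of all
    harmonics align at the glottal pulses ("peaky" speech, in broadband and
    multiband variants), and derives auditory brainstem and middle latency
    responses from EEG by weighted frequency-domain deconvolution against
    pulse-train regressors.  Includes the trapezoid octave filter bank used
    to split speech into bands, spectral-coherence and SNR quality metrics,
    a power-law model of wave latency versus band center frequency, and a
    synthetic-data generator (speech-like pulse trains, a tri-peak brainstem
    kernel, simulated EEG) so the whole pipeline can be exercised without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
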