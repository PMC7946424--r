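# Shared fixture builders (all generated in code; nothing on disk).

# Strictly periodic pulse train, period in seconds.
periodic_train <- function(period, duration, t0 = 0) {
  seq(t0, duration, by = period)
}

# A short synthetic vowel-ish waveform with known pulses: impulse train
# through two resonators, plus a pinch of noise so spectrogram bins are
# never exactly zero.
toy_voiced_audio <- function(duration = 2, f0 = 110, fs = 44100,
                             seed = 1) {
  times <- periodic_train(1 / f0, duration - 1 / f0, t0 = 0.05)
  n <- round(duration * fs)
  src <- pulses_to_regressor(times, n, fs_eeg = fs)
  x <- src
  for (fm in list(c(600, 90), c(1800, 150))) {
    r <- exp(-pi * fm[2] / fs)
    x <- as.numeric(signal::filter(
      (1 - r), c(1, -2 * r * cos(2 * pi * fm[1] / fs), r^2), x))
  }
  withr::with_seed(seed, x <- x + 1e-5 * stats::rnorm(n))
  list(audio = x / sqrt(mean(x^2)) * 0.01, fs = fs,
       pulses = pulse_train(times, fs_audio = fs, duration = duration))
}

# Assemble a coherence_spectrum object directly (for cutoff unit tests).
fake_coherence <- function(freq, C_matrix) {
  structure(
    list(freq = freq, C = C_matrix,
         pairs = data.frame(a = "x", b = "y")[rep(1, nrow(C_matrix)), ],
         n_slices = 1000L, slice_duration = 1,
         zero_energy_flag = rep(FALSE, nrow(C_matrix))),
    class = "coherence_spectrum")
}

# Response waveform on a lag grid with prescribed values.
fake_response <- function(w, fs = 10000, lag0_frac = 0.5,
                          provenance = character()) {
  n <- length(w)
  lag <- (seq_len(n) - 1L - round(n * lag0_frac)) / fs
  peakyspeech:::new_response_waveform(w, lag, fs, provenance)
}
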