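# Synthetic study material: speech-like audio with known glottal pulses
# (narrator-statistics generator) and linearly simulated EEG (regressor
# convolved with a tri-peak brainstem kernel plus pink noise), so every
# pipeline stage can be exercised and validated without recordings.

# ---- narrator specification ------------------------------------------------

#' Narrator statistics for the speech-like generator
#'
#' Presets reproduce the aggregate statistics of the two audiobook
#' narrators used with this paradigm: voiced fundamental 115.1 +/- 6.7 Hz
#' within 60--350 Hz and an overall rate of 69.1 pulses/s over a 64 s
#' segment including pauses (male-like), or 198.1 +/- 20 Hz within
#' 90--500 Hz at 110.8 pulses/s (female-like).
#'
#' Voiced segment durations are log-normal (median `voiced_median_s`,
#' log-SD `dur_sdlog`); unvoiced gaps are log-normal with an occasional
#' fixed pause (`pause_prob`, `pause_dur_s`, pauses already truncated to
#' 0.5 s). The unvoiced mean is not a free parameter: it is solved in
#' closed form so that the expected overall pulse rate equals
#' `target_rate`, using pulses-per-voiced-segment \eqn{\approx f_0 D + 1/2}
#' (first pulse at the segment start plus the integer part of the
#' accumulated cycles).
#'
#' @param narrator `"male"` or `"female"` preset.
#' @param voiced_f0_mean,voiced_f0_sd Voiced fundamental mean and SD in Hz.
#' @param f0_bounds Admissible fundamental range in Hz.
#' @param target_rate,rate_sd Overall pulses/s (including pauses) and its
#'   between-segment SD.
#' @param voiced_median_s Median voiced segment duration in seconds.
#' @param dur_sdlog Log-SD of the segment-duration log-normals.
#' @param pause_prob Probability that an unvoiced gap is a sentence pause.
#' @param pause_dur_s Pause duration in seconds (0.5, the truncation limit).
#' @param f0_sdlog_fast,f0_tau_fast_s Log-SD and correlation time of the
#'   fast prosodic meander of the fundamental (defaults 0.18 and 0.4 s,
#'   typical of read speech). `voiced_f0_sd` is the *across-segment* SD of
#'   the mean voiced rate, matching how the narrator statistics are
#'   reported; the instantaneous pitch range is governed by these log-scale
#'   parameters.
#' @param f0_sdlog_slow,f0_tau_slow_s Log-SD and correlation time of the
#'   slow (across-segment) pitch drift (defaults 0.05 and 20 s).
#' @return An object of class `narrator_spec`.
#' @export
narrator_spec <- function(narrator = c("male", "female"),
                          voiced_f0_mean = NULL, voiced_f0_sd = NULL,
                          f0_bounds = NULL, target_rate = NULL,
                          rate_sd = NULL, voiced_median_s = NULL,
                          dur_sdlog = 0.5, pause_prob = 0.1,
                          pause_dur_s = 0.5, f0_sdlog_fast = 0.18,
                          f0_tau_fast_s = 0.4, f0_sdlog_slow = 0.05,
                          f0_tau_slow_s = 20) {
  narrator <- match.arg(narrator)
  preset <- switch(narrator,
    male = list(f0 = 115.1, f0_sd = 6.7, bounds = c(60, 350),
                rate = 69.1, rate_sd = 5.7, vmed = 0.250),
    female = list(f0 = 198.1, f0_sd = 20, bounds = c(90, 500),
                  rate = 110.8, rate_sd = 11.4, vmed = 0.220))
  f0 <- voiced_f0_mean %||% preset$f0
  f0_sd <- voiced_f0_sd %||% preset$f0_sd
  bounds <- f0_bounds %||% preset$bounds
  rate <- target_rate %||% preset$rate
  rate_sd <- rate_sd %||% preset$rate_sd
  vmed <- voiced_median_s %||% preset$vmed
  if (rate >= f0)
    stop("infeasible spec: overall pulse rate must be below the voiced f0")
  if (bounds[1] > f0 - 2 * f0_sd || bounds[2] < f0 + 2 * f0_sd)
    stop("f0 bounds must contain the mean +/- 2 SD")
  v_mean <- vmed * exp(dur_sdlog^2 / 2)
  # Solve E[gap] so that E[pulses]/E[cycle length] = target rate.
  gap_eff <- (f0 * v_mean + 0.5) / rate - v_mean
  u_mean <- (gap_eff - pause_prob * pause_dur_s) / (1 - pause_prob)
  if (u_mean <= 0.025)
    stop("infeasible spec: implied unvoiced gaps shorter than 25 ms")
  structure(
    list(narrator = narrator, voiced_f0_mean = f0, voiced_f0_sd = f0_sd,
         f0_bounds = bounds, target_rate = rate, rate_sd = rate_sd,
         voiced_median_s = vmed, unvoiced_median_s =
           u_mean * exp(-dur_sdlog^2 / 2),
         dur_sdlog = dur_sdlog, pause_prob = pause_prob,
         pause_dur_s = pause_dur_s, f0_sdlog_fast = f0_sdlog_fast,
         f0_tau_fast_s = f0_tau_fast_s, f0_sdlog_slow = f0_sdlog_slow,
         f0_tau_slow_s = f0_tau_slow_s),
    class = "narrator_spec")
}

#' @export
print.narrator_spec <- function(x, ...) {
  cat(sprintf(
    "<narrator_spec> %s: f0 %.1f +/- %.1f Hz in [%g, %g], target %.1f pulses/s\n",
    x$narrator, x$voiced_f0_mean, x$voiced_f0_sd, x$f0_bounds[1],
    x$f0_bounds[2], x$target_rate))
  invisible(x)
}

# ---- speech-like generator -------------------------------------------------

#' Generate speech-like audio with known glottal pulses
#'
#' Alternates voiced and unvoiced segments per the narrator spec. Within a
#' voiced segment, pulses are laid down by integrating a slowly meandering
#' fundamental (mean-reverting around the narrator mean, clipped to the
#' bounds), with the first pulse at the segment start. Voiced audio is the
#' pulse train shaped by a cascade of formant-like resonators; unvoiced
#' audio is band-limited noise; sentence pauses are silent. The waveform is
#' scaled to RMS 0.01 (the digital storage scale used for stimulus
#' presentation).
#'
#' @param spec A [narrator_spec()].
#' @param duration Duration in seconds (>= 1).
#' @param seed Integer seed (mandatory: the generator is stochastic).
#' @param audio If `FALSE`, skip waveform synthesis and return only pulses
#'   and segmentation (much faster; sufficient for coherence analyses and
#'   EEG simulation).
#' @param fs_audio Audio sampling rate in Hz.
#' @return A list with `audio` (or `NULL`), `fs`, `pulses` (a
#'   [pulse_train()]), `seg` (a [segment_voiced()] segmentation of the true
#'   pulses) and `voiced_intervals` (the generated segment table).
#' @export
synth_speech_like <- function(spec, duration, seed, audio = TRUE,
                              fs_audio = 44100) {
  stopifnot(inherits(spec, "narrator_spec"))
  if (duration < 1) stop("duration must be at least 1 s")
  with_seed(seed, {
    iv <- draw_segments(spec, duration)
    f0g <- draw_f0_contour(spec, duration)
    times <- unlist(lapply(seq_len(nrow(iv)), function(k)
      pulses_in_segment(iv$start[k], iv$end[k], f0g)))
    pt <- pulse_train(times, fs_audio = fs_audio, duration = duration,
                      f0_bounds = spec$f0_bounds)
    seg <- segment_voiced(times)
    wav <- if (audio) render_audio(pt, seg, iv, fs_audio) else NULL
    list(audio = wav, fs = fs_audio, pulses = pt, seg = seg,
         voiced_intervals = iv)
  })
}

# Alternating unvoiced gap / voiced segment table covering `duration`.
draw_segments <- function(spec, duration) {
  start <- numeric(0); end <- numeric(0); pause <- logical(0)
  t <- 0
  repeat {
    is_pause <- stats::runif(1) < spec$pause_prob
    gap <- if (is_pause) spec$pause_dur_s else
      max(0.025, stats::rlnorm(1, log(spec$unvoiced_median_s),
                               spec$dur_sdlog))
    v <- max(0.04, stats::rlnorm(1, log(spec$voiced_median_s),
                                 spec$dur_sdlog))
    s <- t + gap
    if (s >= duration - 0.04) break
    e <- min(s + v, duration - 1e-3)
    start <- c(start, s); end <- c(end, e); pause <- c(pause, is_pause)
    t <- e
    if (e >= duration - 0.05) break
  }
  data.frame(start = start, end = end, after_pause = pause)
}

# Fundamental contour sampled at 100 Hz: log-domain meander with a fast
# prosodic component and a slow across-segment drift, each mean-reverting,
# around a median chosen so the arithmetic mean equals the narrator mean.
# Clipped to the narrator's f0 bounds.
draw_f0_contour <- function(spec, duration) {
  fsg <- 100
  n <- as.integer(ceiling(duration * fsg)) + 2L
  dt <- 1 / fsg
  ou <- function(sdev, tau) {
    k <- dt / tau
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sdev)
    innov <- sdev * sqrt(2 * k)
    eps <- stats::rnorm(n - 1L)
    for (i in 2:n) x[i] <- x[i - 1L] * (1 - k) + innov * eps[i - 1L]
    x
  }
  s2 <- spec$f0_sdlog_fast^2 + spec$f0_sdlog_slow^2
  lmed <- log(spec$voiced_f0_mean) - s2 / 2
  f <- exp(lmed + ou(spec$f0_sdlog_fast, spec$f0_tau_fast_s) +
             ou(spec$f0_sdlog_slow, spec$f0_tau_slow_s))
  f <- pmin(pmax(f, spec$f0_bounds[1]), spec$f0_bounds[2])
  list(t = (seq_len(n) - 1L) * dt, f = f)
}

# Pulse times in [s, e]: first pulse at s, then crossings of the
# accumulated cycle count of the local fundamental.
pulses_in_segment <- function(s, e, f0g) {
  tg <- seq(s, e, by = 1e-3)
  if (length(tg) < 2L) return(s)
  fg <- stats::approx(f0g$t, f0g$f, xout = tg, rule = 2)$y
  ph <- c(0, cumsum((fg[-1] + fg[-length(fg)]) / 2) * diff(tg))
  m <- seq(0, floor(ph[length(ph)]))
  stats::approx(ph + seq_along(ph) * 1e-9, tg, xout = m, rule = 2)$y
}

# Formant-shaped pulse train plus band-limited noise in unvoiced gaps.
render_audio <- function(pt, seg, iv, fs) {
  n <- as.integer(round(pt$duration * fs))
  src <- pulses_to_regressor(pt$times, n, fs_eeg = fs)
  voiced <- src
  for (fm in list(c(500, 80), c(1500, 120), c(2500, 200))) {
    r <- exp(-pi * fm[2] / fs)
    voiced <- as.numeric(signal::filter(
      (1 - r), c(1, -2 * r * cos(2 * pi * fm[1] / fs), r^2), voiced))
  }
  mixer <- build_mixer(seg, fs, n)
  noise <- as.numeric(signal::filter(
    signal::butter(2, c(2000, 8000) / (fs / 2), type = "pass"),
    stats::rnorm(n)))
  noise <- noise / stats::sd(noise) * 0.3 * stats::sd(voiced)
  # silence during sentence pauses (the gap preceding a marked segment)
  for (k in which(iv$after_pause)) {
    i0 <- max(1L, as.integer(round((iv$start[k] - 0.45) * fs)))
    i1 <- as.integer(round((iv$start[k] - 0.02) * fs))
    if (i1 >= i0) noise[i0:i1] <- 0
  }
  out <- (1 - mixer) * voiced + mixer * noise
  out / sqrt(mean(out^2)) * 0.01
}

# ---- brainstem kernel ------------------------------------------------------

#' Tri-peak brainstem response kernel
#'
#' Synthetic impulse response with Gabor-like bumps at the canonical
#' speech-evoked wave I, III and V latencies (3.23, 5.51 and 7.22 ms by
#' default, wave V dominant). Mirroring the construction used for linear
#' EEG simulation, the kernel is zeroed before the start of wave I
#' (1.6 ms), Hann-windowed over 0--16 ms, peak-normalized, and centered on
#' a -16..+16 ms lag axis.
#'
#' @param wave_latencies_ms Component latencies in ms (increasing,
#'   all > 1.6).
#' @param amplitudes Relative component amplitudes (default
#'   `c(0.5, 0.4, 1)`).
#' @param widths_ms Component FWHM in ms (default `c(0.5, 0.7, 1.0)`).
#' @param fs_eeg Sampling rate in Hz.
#' @return An object of class `abr_kernel` with `kernel`, `lag` (seconds)
#'   and the construction parameters.
#' @export
make_abr_kernel <- function(wave_latencies_ms = c(3.23, 5.51, 7.22),
                            amplitudes = c(0.5, 0.4, 1),
                            widths_ms = c(0.5, 0.7, 1.0), fs_eeg = 10000) {
  if (is.unsorted(wave_latencies_ms, strictly = TRUE))
    stop("wave latencies must be increasing")
  if (any(wave_latencies_ms <= 1.6))
    stop("wave latencies must exceed 1.6 ms (start of wave I)")
  n_half <- as.integer(round(0.016 * fs_eeg))
  lag <- (-n_half):(n_half - 1L) / fs_eeg
  t_ms <- lag * 1000
  k <- numeric(length(lag))
  for (j in seq_along(wave_latencies_ms)) {
    sig <- widths_ms[j] / 2.355          # FWHM -> Gaussian SD
    k <- k + amplitudes[j] *
      exp(-0.5 * ((t_ms - wave_latencies_ms[j]) / sig)^2) *
      cos(2 * pi * (t_ms - wave_latencies_ms[j]) / (3 * widths_ms[j]))
  }
  k[t_ms < 1.6] <- 0
  pos <- t_ms >= 0 & t_ms <= 16
  k[pos] <- k[pos] * 0.5 * (1 - cos(2 * pi * t_ms[pos] / 16))
  k[!pos & t_ms > 0] <- 0
  k <- k / max(abs(k))
  structure(list(kernel = k, lag = lag, fs = fs_eeg,
                 latencies_ms = wave_latencies_ms, amplitudes = amplitudes,
                 widths_ms = widths_ms),
            class = "abr_kernel")
}

#' @export
print.abr_kernel <- function(x, ...) {
  cat(sprintf("<abr_kernel> waves at %s ms, fs %g Hz\n",
              paste(x$latencies_ms, collapse = "/"), x$fs))
  invisible(x)
}

# Circular convolution of an epoch with a centered kernel (kernel lag 0
# aligned to the regressor samples).
circular_convolve_kernel <- function(x, kernel) {
  n <- length(x)
  k <- kernel$kernel
  i0 <- which.min(abs(kernel$lag))        # index of lag 0
  kpad <- numeric(n)
  n_pos <- length(k) - i0 + 1L
  kpad[seq_len(n_pos)] <- k[i0:length(k)]
  kpad[n - (i0 - 1L) + seq_len(i0 - 1L)] <- k[seq_len(i0 - 1L)]
  Re(stats::fft(stats::fft(x) * stats::fft(kpad), inverse = TRUE)) / n
}

# ---- EEG simulation --------------------------------------------------------

#' Simulate epoched EEG from a regressor and a kernel
#'
#' Linear EEG model: each epoch is the input (a pulse-train regressor or
#' rectified audio at the EEG rate) circularly convolved with the brainstem
#' kernel, plus pink (1/f) noise and optional power-line harmonics, scaled
#' to the requested per-epoch SNR.
#'
#' @param x Input at the EEG rate: a single numeric vector (recycled across
#'   epochs), a list of per-epoch vectors, or an epochs-by-samples matrix.
#' @param kernel An [make_abr_kernel()] kernel.
#' @param n_epochs Number of epochs (required when `x` is a single vector).
#' @param snr_db Per-epoch SNR in dB, `10*log10(var(signal)/var(noise))`
#'   (default -20, a realistic single-epoch brainstem SNR).
#' @param fs Sampling rate in Hz (must match the kernel).
#' @param line_freqs Power-line components in Hz (e.g.
#'   `c(60, 180, 300, 420)`); empty for none.
#' @param kernel_gain Scalar on the convolved signal (0 simulates
#'   no-response EEG).
#' @param seed Integer seed (mandatory).
#' @return An [epoched_recording()]; the noiseless signal epochs are kept
#'   in attribute `"signal"`.
#' @export
simulate_eeg <- function(x, kernel, n_epochs = NULL, snr_db = -20,
                         fs = 10000, line_freqs = numeric(0),
                         kernel_gain = 1, seed) {
  stopifnot(inherits(kernel, "abr_kernel"))
  if (fs != kernel$fs) stop("fs must match the kernel sampling rate")
  xs <- if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
        else if (is.list(x)) x
        else rep(list(as.numeric(x)),
                 n_epochs %||% stop("n_epochs required for a single vector"))
  n_ep <- length(xs)
  n <- length(xs[[1]])
  with_seed(seed, {
    y <- matrix(0, n_ep, n)
    sig_mat <- matrix(0, n_ep, n)
    tt <- (seq_len(n) - 1L) / fs
    for (i in seq_len(n_ep)) {
      sig <- kernel_gain * circular_convolve_kernel(xs[[i]], kernel)
      noise <- pink_noise(n)
      for (lf in line_freqs)
        noise <- noise + 0.5 * stats::sd(noise) *
          sin(2 * pi * lf * tt + stats::runif(1, 0, 2 * pi))
      v_sig <- stats::var(sig)
      v_target <- if (v_sig > 0) v_sig / 10^(snr_db / 10) else 1
      noise <- noise / stats::sd(noise) * sqrt(v_target)
      sig_mat[i, ] <- sig
      y[i, ] <- sig + noise
    }
    rec <- epoched_recording(y, fs)
    attr(rec, "signal") <- sig_mat
    rec
  })
}

# Unit-variance pink (1/f amplitude) noise via spectral shaping.
pink_noise <- function(n) {
  z <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1L)                # symmetric bin distance
  z <- z / sqrt(f)
  z[1] <- 0
  out <- Re(stats::fft(z, inverse = TRUE)) / n
  out / stats::sd(out)
}
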