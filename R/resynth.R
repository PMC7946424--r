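# Pitch-synchronous harmonic re-synthesis ("peaky" speech): a phase function
# that advances by exactly 2*pi between glottal pulses, harmonics
# re-synthesized from the spectrogram of the unaltered audio with all phases
# aligned at the pulses, and the broadband / multiband assemblies with their
# regressor pulse trains.

MAX_SHIFT_PRIMES <- 25L

# ---- phase function --------------------------------------------------------

#' Build a glottal-pulse phase function
#'
#' Within each voiced segment the unshifted phase is the natural cubic
#' spline through the knots \eqn{\phi(p_i) = 2\pi i}, so phase increases
#' smoothly by \eqn{2\pi} between glottal pulses; outside the outermost
#' pulses it extrapolates linearly at the local fundamental. A static shift
#' adds \eqn{2\pi f_\Delta t}; a dynamic shift adds
#' \eqn{2\pi\int f_\Delta(\tau)d\tau + \theta_\Delta}, where
#' \eqn{f_\Delta(t)} is a slowly varying random process bounded to
#' \eqn{\pm}`dyn_max_hz` and \eqn{\theta_\Delta \sim U(0, 2\pi)}.
#'
#' @param seg A [segment_voiced()] segmentation (carries the pulse times).
#' @param fs Sampling rate of the phase grid in Hz (audio rate for
#'   synthesis; a coarser grid is sufficient for pulse-train generation).
#' @param n_samples Length of the sampled grid.
#' @param f_shift Static fundamental-frequency shift in Hz (default 0).
#' @param dynamic If `TRUE`, use a random dynamic shift instead of the
#'   static one; requires `seed`.
#' @param dyn_max_hz Bound on the dynamic shift magnitude (default 1 Hz).
#' @param seed Integer seed (mandatory for `dynamic = TRUE`).
#' @param lone_f0 Fundamental in Hz assumed for degenerate single-pulse
#'   segments (default 100).
#' @return An object of class `phase_function`: per-segment sampled phase
#'   (`phi`, radians, shift included) and unshifted fundamental (`f0`, Hz)
#'   with the first sample index `i0` (0-based), plus grid metadata.
#' @export
make_phase_function <- function(seg, fs, n_samples, f_shift = 0,
                                dynamic = FALSE, dyn_max_hz = 1,
                                seed = NULL, lone_f0 = 100) {
  stopifnot(inherits(seg, "voiced_segmentation"), fs > 0)
  n_samples <- as.integer(n_samples)
  shift_cum <- NULL
  theta <- 0
  if (dynamic) {
    if (is.null(seed))
      stop("dynamic frequency shifts require an explicit seed")
    dyn <- with_seed(seed, dynamic_shift_track(n_samples, fs, dyn_max_hz))
    shift_cum <- cumsum(dyn$fdelta) / fs   # integral of f_delta(t), Hz*s
    theta <- dyn$theta
  }
  segs <- seg$segments
  out <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    p <- seg$times[segs$i_first[s]:segs$i_last[s]]
    i0 <- max(0L, as.integer(floor(p[1] * fs)))
    i1 <- min(n_samples - 1L, as.integer(ceiling(p[length(p)] * fs)))
    if (i1 < i0) next
    tt <- (i0:i1) / fs
    if (length(p) >= 2L) {
      sf <- stats::splinefun(p, 2 * pi * (seq_along(p) - 1L),
                             method = "natural")
      phi <- sf(tt)
      f0 <- pmax(sf(tt, deriv = 1), 2 * pi * 1e-3) / (2 * pi)
    } else {
      phi <- 2 * pi * lone_f0 * (tt - p[1])
      f0 <- rep(lone_f0, length(tt))
    }
    phi <- cummax(phi)                     # guard monotonicity for inversion
    if (dynamic) {
      phi <- phi + 2 * pi * shift_cum[(i0:i1) + 1L] + theta
    } else if (f_shift != 0) {
      phi <- phi + 2 * pi * f_shift * tt
    }
    out[[s]] <- list(i0 = i0, phi = phi, f0 = f0)
  }
  structure(
    list(segments = out[!vapply(out, is.null, logical(1))],
         fs = fs, n_samples = n_samples, f_shift = f_shift,
         dynamic = dynamic, theta = theta, seed = seed),
    class = "phase_function")
}

# Slowly varying random frequency-shift track: white noise low-passed at
# 0.1 Hz (generated at 100 Hz then interpolated to the phase grid),
# standardized to SD dyn_max_hz/2 and clipped to +/- dyn_max_hz.
dynamic_shift_track <- function(n_samples, fs, dyn_max_hz) {
  fs0 <- 100
  n0 <- max(16L, as.integer(ceiling(n_samples / fs * fs0)) + 2L)
  w <- stats::rnorm(n0)
  lp <- butter_filter(w, 0.1, fs0, "low", order = 1L)
  lp <- lp - mean(lp)
  s <- stats::sd(lp)
  if (s > 0) lp <- lp / s * (dyn_max_hz / 2)
  lp <- pmin(pmax(lp, -dyn_max_hz), dyn_max_hz)
  t0 <- (seq_len(n0) - 1L) / fs0
  fd <- stats::approx(t0, lp, xout = (seq_len(n_samples) - 1L) / fs,
                      rule = 2)$y
  list(fdelta = fd, theta = stats::runif(1, 0, 2 * pi))
}

#' Pulse times of a (possibly shifted) phase function
#'
#' Inverts the sampled phase within each voiced segment: a pulse is placed
#' at every crossing of an integer multiple of \eqn{2\pi}. For an unshifted
#' phase function these are the original glottal pulse times; for shifted
#' phase functions they are the regressor pulse trains of the corresponding
#' band, sharing the voiced onsets/offsets of the original pulses.
#'
#' @param phi A [make_phase_function()] object.
#' @return Numeric vector of pulse times in seconds.
#' @export
phase_pulse_times <- function(phi) {
  stopifnot(inherits(phi, "phase_function"))
  out <- lapply(phi$segments, function(sg) {
    ph <- sg$phi + seq_along(sg$phi) * 1e-9  # break exact ties
    tt <- (sg$i0 + seq_along(ph) - 1L) / phi$fs
    # small tolerance so a crossing exactly on a grid sample is kept
    m_lo <- ceiling((ph[1] - 1e-6) / (2 * pi))
    m_hi <- floor((ph[length(ph)] + 1e-6) / (2 * pi))
    if (m_hi < m_lo) return(numeric(0))
    stats::approx(ph, tt, xout = 2 * pi * (m_lo:m_hi), rule = 2)$y
  })
  sort(unlist(out))
}

# ---- spectrogram sampler ---------------------------------------------------

#' Spectrogram amplitude sampler
#'
#' Short-time magnitude surface of the unaltered speech, queryable at
#' arbitrary (time, frequency) points by bilinear interpolation. The
#' magnitude is scaled so that a unit-amplitude tone at a bin center reads
#' amplitude 1, which makes re-synthesized harmonics come out on the scale
#' of the original waveform.
#'
#' @param audio Numeric waveform.
#' @param fs Sampling frequency in Hz.
#' @param n_window Hann analysis window length in samples (default 1024,
#'   about 23 ms at 44.1 kHz).
#' @param hop Analysis hop in samples (default 110, about 2.5 ms).
#' @return An object of class `spectrogram_sampler`.
#' @export
build_spectrogram_sampler <- function(audio, fs, n_window = 1024L,
                                      hop = 110L) {
  audio <- as.numeric(audio)
  if (length(audio) < n_window)
    stop("audio shorter than one analysis window")
  win <- signal::hanning(n_window)
  sp <- signal::specgram(audio, n = n_window, Fs = fs, window = win,
                         overlap = n_window - hop)
  A <- 2 * abs(sp$S) / sum(win)
  tt <- as.numeric(sp$t) + (n_window / 2) / fs  # window centers
  structure(
    list(A = A, t = tt, f = as.numeric(sp$f), fs = fs,
         time_resolution = hop / fs, freq_resolution = fs / n_window,
         duration = length(audio) / fs),
    class = "spectrogram_sampler")
}

#' Query a spectrogram sampler
#'
#' Bilinear interpolation of the amplitude surface; queries outside the
#' analyzed time span or at/above Nyquist return 0.
#'
#' @param samp A [build_spectrogram_sampler()] object.
#' @param t Numeric vector of query times in seconds.
#' @param f Numeric vector of query frequencies in Hz (recycled with `t`).
#' @return Numeric vector of amplitudes.
#' @export
sample_spectrogram <- function(samp, t, f) {
  stopifnot(inherits(samp, "spectrogram_sampler"))
  n <- max(length(t), length(f))
  t <- rep_len(as.numeric(t), n)
  f <- rep_len(as.numeric(f), n)
  out <- numeric(n)
  inside <- t >= 0 & t <= samp$duration & f >= 0 & f < samp$fs / 2
  if (!any(inside)) return(out)
  tq <- pmin(pmax(t[inside], samp$t[1]), samp$t[length(samp$t)])
  fq <- pmin(pmax(f[inside], samp$f[1]), samp$f[length(samp$f)])
  it <- pmin(pmax(findInterval(tq, samp$t), 1L), length(samp$t) - 1L)
  jf <- pmin(pmax(findInterval(fq, samp$f), 1L), length(samp$f) - 1L)
  wt <- (tq - samp$t[it]) / (samp$t[it + 1L] - samp$t[it])
  wf <- (fq - samp$f[jf]) / (samp$f[jf + 1L] - samp$f[jf])
  nf <- nrow(samp$A)
  a00 <- samp$A[jf + (it - 1L) * nf]
  a01 <- samp$A[jf + it * nf]
  a10 <- samp$A[jf + 1L + (it - 1L) * nf]
  a11 <- samp$A[jf + 1L + it * nf]
  out[inside] <- (1 - wt) * ((1 - wf) * a00 + wf * a10) +
    wt * ((1 - wf) * a01 + wf * a11)
  out
}

# ---- harmonic synthesis ----------------------------------------------------

#' Re-synthesize voiced speech with pulse-aligned harmonic phases
#'
#' Sums the fundamental and harmonic waveforms
#' \eqn{h_k(t) = A[t, (k+1)f_0(t)]\cos[(k+1)\phi(t)]} within each voiced
#' segment, including harmonics while \eqn{(k+1)f_0(t) < f_{max}}. Because
#' \eqn{\phi} advances by \eqn{2\pi} between pulses, all harmonic phases
#' align at every glottal pulse and the waveform is maximally impulse-like
#' there while keeping the spectrotemporal envelope of the original speech.
#'
#' @param samp A [build_spectrogram_sampler()] of the unaltered audio.
#' @param phi A [make_phase_function()] built on the audio grid.
#' @param f_max Highest synthesized frequency in Hz (default 12000; the
#'   band filters then impose the 8 / 11.36 kHz mixing limits).
#' @return Numeric waveform of length `phi$n_samples` (zero outside voiced
#'   segments).
#' @export
synthesize_peaky_voiced <- function(samp, phi, f_max = 12000) {
  stopifnot(inherits(samp, "spectrogram_sampler"),
            inherits(phi, "phase_function"))
  if (f_max > phi$fs / 2)
    stop("f_max must not exceed the Nyquist frequency of the phase grid")
  out <- numeric(phi$n_samples)
  for (sg in phi$segments) {
    tt <- (sg$i0 + seq_along(sg$phi) - 1L) / phi$fs
    wave <- numeric(length(tt))
    kmax <- max(0L, as.integer(floor(f_max / min(sg$f0))) - 1L)
    for (k in 0:kmax) {
      fk <- (k + 1) * sg$f0
      m <- fk < f_max
      if (!any(m)) break
      wave[m] <- wave[m] +
        sample_spectrogram(samp, tt[m], fk[m]) * cos((k + 1) * sg$phi[m])
    }
    idx <- sg$i0 + seq_along(wave)
    out[idx] <- out[idx] + wave
  }
  out
}

# ---- assemblies ------------------------------------------------------------

new_resynth_result <- function(audio, fs, regressors, fake_regressors,
                               shifts, fake_shifts, mixer, seg, bank, mode) {
  structure(
    list(audio = audio, fs = fs, regressors = regressors,
         fake_regressors = fake_regressors, shifts = shifts,
         fake_shifts = fake_shifts, mixer = mixer, seg = seg, bank = bank,
         mode = mode),
    class = "resynth_result")
}

#' @export
print.resynth_result <- function(x, ...) {
  n_ch <- if (is.matrix(x$audio)) ncol(x$audio) else 1L
  cat(sprintf(
    "<resynth_result> %s peaky speech: %.2f s, %d channel(s), %d true + %d fake pulse train(s)\n",
    x$mode, (if (is.matrix(x$audio)) nrow(x$audio) else length(x$audio)) / x$fs,
    n_ch, length(x$regressors), length(x$fake_regressors)))
  invisible(x)
}

#' Make broadband peaky speech
#'
#' Re-synthesizes the voiced portions of `audio` with harmonic phases
#' aligned at the glottal pulses, low-pass limits the peaky part with the
#' bank's broadband limit filter, adds back the unaltered top octave band,
#' and crossfades with the unaltered speech through the voiced/unvoiced
#' mixer. The regressor is the (smoothed) glottal pulse train itself.
#'
#' @param audio Numeric waveform.
#' @param pulses A [pulse_train()] extracted from the same audio.
#' @param bank Optional [design_band_filters()] bank; defaults to the
#'   four-edge octave bank `c(1000, 2000, 4000, 8000)` at the audio rate,
#'   giving the 8 kHz peaky limit.
#' @param f_max Highest synthesized harmonic frequency in Hz.
#' @param smooth Apply [smooth_pulse_times()] first (default `TRUE`).
#' @return A `resynth_result` with the peaky audio, the regressor pulse
#'   train, the mixer and the segmentation.
#' @export
make_broadband_peaky <- function(audio, pulses, bank = NULL, f_max = 12000,
                                 smooth = TRUE) {
  stopifnot(inherits(pulses, "pulse_train"))
  audio <- as.numeric(audio)
  fs <- pulses$fs_audio
  n <- length(audio)
  if (abs(n / fs - pulses$duration) > 0.05)
    stop("audio duration does not match the pulse train's stated duration")
  bank <- bank %||% design_band_filters(fs = fs)
  times <- if (smooth) smooth_pulse_times(pulses$times) else pulses$times
  seg <- segment_voiced(times)
  mixer <- build_mixer(seg, fs, n)
  if (!length(times)) {
    return(new_resynth_result(audio, fs, list(band1 = numeric(0)), list(),
                              0, numeric(0), mixer, seg, bank, "broadband"))
  }
  samp <- build_spectrogram_sampler(audio, fs)
  phi <- make_phase_function(seg, fs, n)
  peaky <- synthesize_peaky_voiced(samp, phi, f_max)
  limit <- broadband_limit_filter(bank)
  peaky_lp <- conv_centered(peaky, limit$ir[, 1])
  high <- apply_band_filter(audio, bank, bank$n_bands)
  out <- mixer * audio + (1 - mixer) * (peaky_lp + high)
  new_resynth_result(out, fs, list(band1 = times), list(), 0, numeric(0),
                     mixer, seg, bank, "broadband")
}

# Static shift sequence: lowest band unshifted, then sqrt(prime) - 1 Hz for
# successive primes; fake trains continue the sequence, half assigned below
# the original fundamental (negative) and half above the highest true shift.
static_shift_sequence <- function(n_true, n_fake) {
  n_primes <- n_true - 1L + n_fake
  if (n_primes > MAX_SHIFT_PRIMES)
    stop("requested bands exceed the available prime shift table")
  pr <- sqrt(first_primes(max(n_primes, 1L))) - 1
  true_shifts <- c(0, if (n_true > 1L) pr[seq_len(n_true - 1L)])
  fake <- if (n_fake > 0L) pr[n_true - 1L + seq_len(n_fake)] else numeric(0)
  if (n_fake > 0L) {
    n_neg <- n_fake %/% 2L
    fake <- c(-fake[seq_len(n_neg)], fake[(n_neg + 1L):n_fake])
  }
  list(true_shifts = true_shifts, fake_shifts = fake)
}

#' Make multiband peaky speech
#'
#' Repeats the peaky re-synthesis once per frequency band with a slightly
#' shifted fundamental per band (static \eqn{\sqrt{prime}-1} Hz shifts with
#' the lowest band unshifted, or random dynamic shifts bounded to
#' \eqn{\pm 1} Hz), band-pass filters each re-synthesis to its octave band,
#' sums the bands, and crossfades with the unaltered speech plus its
#' unaltered top band. Returns one regressor pulse train per band and ear,
#' plus `n_fake` "fake" pulse trains whose shifts continue the sequence but
#' which are never synthesized into audio (used to estimate the common
#' response component).
#'
#' @inheritParams make_broadband_peaky
#' @param shift_mode `"static"` or `"dynamic"`.
#' @param n_fake Number of fake pulse trains (default 6).
#' @param ears 1 (diotic, mono output) or 2 (dichotic, stereo output with
#'   independent shifts per ear; trains ordered ear-major, band-minor).
#' @param seed Integer seed, required for `shift_mode = "dynamic"`.
#' @return A `resynth_result`; `audio` is a vector (`ears = 1`) or an
#'   `n x 2` matrix (`ears = 2`).
#' @export
make_multiband_peaky <- function(audio, pulses, bank = NULL,
                                 shift_mode = c("static", "dynamic"),
                                 n_fake = 6L, ears = 1L, seed = NULL,
                                 f_max = 12000, smooth = TRUE) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(inherits(pulses, "pulse_train"), ears %in% c(1L, 2L))
  audio <- as.numeric(audio)
  fs <- pulses$fs_audio
  n <- length(audio)
  if (abs(n / fs - pulses$duration) > 0.05)
    stop("audio duration does not match the pulse train's stated duration")
  bank <- bank %||% design_band_filters(fs = fs)
  n_bands_synth <- bank$n_bands - 1L
  n_true <- n_bands_synth * as.integer(ears)
  if (shift_mode == "dynamic" && is.null(seed))
    stop("dynamic frequency shifts require an explicit seed")

  times <- if (smooth) smooth_pulse_times(pulses$times) else pulses$times
  seg <- segment_voiced(times)
  mixer <- build_mixer(seg, fs, n)
  samp <- build_spectrogram_sampler(audio, fs)
  high <- apply_band_filter(audio, bank, bank$n_bands)

  if (shift_mode == "static") {
    sh <- static_shift_sequence(n_true, n_fake)
  } else {
    sh <- list(true_shifts = rep(NA_real_, n_true),
               fake_shifts = rep(NA_real_, n_fake))
  }
  # Deterministic sub-seeds per train for dynamic mode.
  train_seed <- function(j) if (is.null(seed)) NULL else
    (as.integer(seed) + 1009L * j) %% .Machine$integer.max

  regressors <- list()
  out <- matrix(0, n, ears)
  j <- 0L
  for (ear in seq_len(ears)) {
    band_sum <- numeric(n)
    for (b in seq_len(n_bands_synth)) {
      j <- j + 1L
      phi <- if (shift_mode == "static")
        make_phase_function(seg, fs, n, f_shift = sh$true_shifts[j])
      else
        make_phase_function(seg, fs, n, dynamic = TRUE,
                            seed = train_seed(j))
      nm <- sprintf("ear%d_band%d", ear, b)
      regressors[[nm]] <- phase_pulse_times(phi)
      peaky <- synthesize_peaky_voiced(samp, phi, f_max)
      band_sum <- band_sum + apply_band_filter(peaky, bank, b)
    }
    out[, ear] <- mixer * audio + (1 - mixer) * (band_sum + high)
  }

  fakes <- list()
  for (k in seq_len(n_fake)) {
    phi <- if (shift_mode == "static")
      make_phase_function(seg, fs, n, f_shift = sh$fake_shifts[k])
    else
      make_phase_function(seg, fs, n, dynamic = TRUE,
                          seed = train_seed(n_true + k))
    fakes[[sprintf("fake%d", k)]] <- phase_pulse_times(phi)
  }

  new_resynth_result(if (ears == 1L) out[, 1] else out, fs, regressors,
                     fakes, sh$true_shifts, sh$fake_shifts, mixer, seg,
                     bank, sprintf("multiband_%s", shift_mode))
}

#' Multiband regressor pulse trains without audio synthesis
#'
#' Generates the true and fake pulse trains of a multiband design directly
#' from a pulse train, skipping the (expensive) audio re-synthesis. Used
#' for pulse-train coherence analyses and EEG simulation, where only the
#' regressors matter.
#'
#' @inheritParams make_multiband_peaky
#' @param pulses A [pulse_train()].
#' @param n_bands Number of synthesized bands per ear.
#' @param fs_grid Sampling rate of the phase inversion grid in Hz
#'   (default 2000; pulse-time accuracy is set by interpolation, not by the
#'   grid itself).
#' @return A list with `trains` (named list of pulse-time vectors,
#'   ear-major), `fakes`, `shifts` and `fake_shifts`.
#' @export
multiband_pulse_trains <- function(pulses, n_bands = 4L, ears = 1L,
                                   shift_mode = c("static", "dynamic"),
                                   n_fake = 6L, seed = NULL,
                                   fs_grid = 2000, smooth = TRUE) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(inherits(pulses, "pulse_train"))
  if (shift_mode == "dynamic" && is.null(seed))
    stop("dynamic frequency shifts require an explicit seed")
  times <- if (smooth) smooth_pulse_times(pulses$times) else pulses$times
  seg <- segment_voiced(times)
  n_samples <- as.integer(ceiling(pulses$duration * fs_grid)) + 1L
  n_true <- as.integer(n_bands) * as.integer(ears)
  sh <- if (shift_mode == "static") static_shift_sequence(n_true, n_fake)
        else list(true_shifts = rep(NA_real_, n_true),
                  fake_shifts = rep(NA_real_, n_fake))
  train_seed <- function(j) if (is.null(seed)) NULL else
    (as.integer(seed) + 1009L * j) %% .Machine$integer.max
  one <- function(j, shift) {
    phi <- if (shift_mode == "static")
      make_phase_function(seg, fs_grid, n_samples, f_shift = shift)
    else
      make_phase_function(seg, fs_grid, n_samples, dynamic = TRUE,
                          seed = train_seed(j))
    phase_pulse_times(phi)
  }
  trains <- list()
  j <- 0L
  for (ear in seq_len(ears)) for (b in seq_len(n_bands)) {
    j <- j + 1L
    trains[[sprintf("ear%d_band%d", ear, b)]] <- one(j, sh$true_shifts[j])
  }
  fakes <- list()
  for (k in seq_len(n_fake))
    fakes[[sprintf("fake%d", k)]] <- one(n_true + k, sh$fake_shifts[k])
  list(trains = trains, fakes = fakes, shifts = sh$true_shifts,
       fake_shifts = sh$fake_shifts)
}

# ---- polarity alternation and epoching ------------------------------------

#' Alternate stimulus polarity in near-silent regions
#'
#' Extracts the speech envelope with a causal first-order 6 Hz low-pass on
#' the absolute waveform, flips the sign of the stimulus each time the
#' envelope drops below 1% of its median value, and smooths the resulting
#' \eqn{\pm 1} function with a causal first-order 10 kHz low-pass before
#' multiplying. Because flips happen only in near-silence, the signal
#' energy is essentially preserved while any stimulus artifact in the EEG
#' averages out.
#'
#' @param audio Numeric waveform.
#' @param fs Sampling frequency in Hz (must exceed 20 kHz for the 10 kHz
#'   smoothing filter).
#' @return A list with `audio` (polarity-alternated waveform) and
#'   `flip_indices` (sample indices where the sign function flips).
#' @export
alternate_polarity <- function(audio, fs) {
  audio <- as.numeric(audio)
  if (!length(audio)) stop("audio must be nonempty")
  if (fs <= 20000)
    stop("fs must exceed 20 kHz for the 10 kHz smoothing filter")
  # warm the causal envelope filter up on a mirrored lead-in so the initial
  # transient does not register as silence
  nw <- min(length(audio), as.integer(fs / 2))
  ax <- abs(audio)
  env <- butter_filter(c(rev(ax[seq_len(nw)]), ax), 6, fs, "low",
                       1L)[-seq_len(nw)]
  thr <- 0.01 * stats::median(env)
  below <- env < thr
  flips <- which(below & !c(FALSE, below[-length(below)]))
  ind <- integer(length(audio))
  ind[flips] <- 1L
  sgn <- 1 - 2 * (cumsum(ind) %% 2)
  smoothed <- butter_filter(sgn, 10000, fs, "low", 1L)
  list(audio = audio * smoothed, flip_indices = flips)
}

#' Cut continuous audio into presentation epochs
#'
#' Truncates silent pauses to `pause_limit` seconds, then segments the
#' audio into `epoch_dur`-second epochs advancing by `advance` seconds (so
#' the last `epoch_dur - advance` seconds of one epoch repeat at the start
#' of the next) and applies raised-cosine fade-in/out of `fade` seconds to
#' every epoch.
#'
#' @param audio Numeric waveform.
#' @param fs Sampling frequency in Hz.
#' @param epoch_dur Epoch duration in seconds (default 64).
#' @param advance Epoch advance in seconds (default 60, i.e. 4 s overlap).
#' @param fade Raised-cosine fade duration in seconds (default 1).
#' @param pause_limit Maximum retained pause duration in seconds
#'   (default 0.5).
#' @return A matrix of `n_epochs x (epoch_dur*fs)` samples.
#' @export
prepare_epochs <- function(audio, fs, epoch_dur = 64, advance = 60,
                           fade = 1, pause_limit = 0.5) {
  audio <- as.numeric(audio)
  audio <- truncate_pauses(audio, fs, pause_limit)
  n_ep_samp <- as.integer(round(epoch_dur * fs))
  n_adv <- as.integer(round(advance * fs))
  if (length(audio) < n_ep_samp) {
    warning("audio shorter than one epoch after pause truncation; zero-padding")
    audio <- c(audio, numeric(n_ep_samp - length(audio)))
  }
  n_epochs <- max(1L, as.integer(ceiling((length(audio) - n_ep_samp) / n_adv)) + 1L)
  fade_n <- as.integer(round(fade * fs))
  ramp <- 0.5 * (1 - cos(pi * (0:(fade_n - 1L)) / fade_n))
  out <- matrix(0, n_epochs, n_ep_samp)
  for (e in seq_len(n_epochs)) {
    i0 <- (e - 1L) * n_adv + 1L
    chunk <- audio[i0:min(i0 + n_ep_samp - 1L, length(audio))]
    chunk <- c(chunk, numeric(n_ep_samp - length(chunk)))
    chunk[seq_len(fade_n)] <- chunk[seq_len(fade_n)] * ramp
    chunk[n_ep_samp - fade_n + seq_len(fade_n)] <-
      chunk[n_ep_samp - fade_n + seq_len(fade_n)] * rev(ramp)
    out[e, ] <- chunk
  }
  out
}

# Truncate runs of near-silence (6 Hz envelope below 1% of its median)
# longer than `pause_limit` seconds, keeping the first `pause_limit` s.
truncate_pauses <- function(audio, fs, pause_limit) {
  if (!length(audio) || all(audio == 0)) {
    n_keep <- min(length(audio), as.integer(round(pause_limit * fs)))
    return(audio[seq_len(n_keep)])
  }
  nw <- min(length(audio), as.integer(fs / 2))
  ax <- abs(audio)
  env <- butter_filter(c(rev(ax[seq_len(nw)]), ax), 6, fs, "low",
                       1L)[-seq_len(nw)]
  sil <- env < 0.01 * stats::median(env)
  r <- rle(sil)
  keep <- rep(TRUE, length(audio))
  pos <- cumsum(c(1L, r$lengths))
  lim <- as.integer(round(pause_limit * fs))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > lim) {
      i0 <- pos[k] + lim
      keep[i0:(pos[k] + r$lengths[k] - 1L)] <- FALSE
    }
  }
  audio[keep]
}
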