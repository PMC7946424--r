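# Trapezoid octave filter bank: power trapezoids specified in the frequency
# domain (linear in log2 frequency), converted to short Nuttall-windowed
# impulse responses. Adjacent bands cross at half power so the designed
# powers sum to 1 across the covered range.

#' Design the trapezoid octave filter bank
#'
#' Filters are specified as power trapezoids on a fine FFT frequency grid:
#' each shared cutoff carries a roll-off of `rolloff` octaves (power ramping
#' linearly in log2 frequency across +/- `rolloff/2` octaves around the
#' edge), so adjacent bands cross at half power (amplitude \eqn{1/\sqrt 2})
#' and designed powers sum to exactly 1. For the lowest band all frequencies
#' below its upper cutoff pass (amplitude 1), and likewise above the lower
#' cutoff for the highest band. The amplitude response is the square root of
#' the specified power. Impulse responses are obtained by IFFT, circularly
#' shifted so time zero is centered, truncated to `ir_duration` and Nuttall
#' windowed; the realized magnitude response is then re-measured by FFT of
#' the kernels.
#'
#' @param cutoffs Strictly increasing interior band edges in Hz (e.g.
#'   `c(1000, 2000, 4000, 8000)` gives the five bands 0--1, 1--2, 2--4,
#'   4--8 and 8+ kHz).
#' @param rolloff Total roll-off width at each edge, in octaves
#'   (default 0.5).
#' @param fs Sampling frequency in Hz.
#' @param ir_duration Impulse-response duration in seconds (default 0.005).
#' @return An object of class `band_filter_bank` with elements `cutoffs`,
#'   `fs`, `freq` (design grid), `designed_amp` (grid x band amplitude
#'   matrix), `ir` (samples x band kernel matrix, odd length, centered),
#'   `realized_mag`, `centers` (geometric band centers in Hz) and `n_bands`.
#' @export
design_band_filters <- function(cutoffs = c(1000, 2000, 4000, 8000),
                                rolloff = 0.5, fs = 44100,
                                ir_duration = 0.005) {
  cutoffs <- as.numeric(cutoffs)
  fs <- as.numeric(fs)                     # avoid integer overflow on grids
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0))
    stop("cutoffs must be strictly increasing and positive")
  if (any(cutoffs >= fs / 2))
    stop("cutoffs must lie below the Nyquist frequency")
  L <- round(ir_duration * fs)
  if (L < 8) stop("ir_duration*fs must be at least 8 samples")
  if (L %% 2L == 0L) L <- L + 1L          # odd length -> integer group delay
  h <- rolloff / 2
  # Adjacent roll-off regions must not collide inside a band.
  inner <- cutoffs[-length(cutoffs)] * 2^h
  outer <- cutoffs[-1] * 2^(-h)
  if (any(inner >= outer))
    stop("roll-off regions overlap: bands are narrower than the roll-off")
  n_bands <- length(cutoffs) + 1L

  # Design grid: >= 2 s of samples so trapezoid corners resolve to < 1 Hz.
  nfft <- stats::nextn(2 * fs, 2)
  freq <- (0:(nfft / 2)) * fs / nfft

  # Power ramp 0 -> 1 across [e*2^-h, e*2^h], linear in log2(f).
  ramp_up <- function(e) {
    r <- (log2(pmax(freq, .Machine$double.eps)) - (log2(e) - h)) / (2 * h)
    pmin(pmax(r, 0), 1)
  }
  pow <- matrix(0, length(freq), n_bands)
  for (b in seq_len(n_bands)) {
    p_lo <- if (b == 1L) 1 else ramp_up(cutoffs[b - 1L])
    p_hi <- if (b == n_bands) 1 else 1 - ramp_up(cutoffs[b])
    pow[, b] <- p_lo * p_hi
  }
  amp <- sqrt(pow)

  ir <- matrix(0, L, n_bands)
  half <- (L - 1L) %/% 2L
  win <- nuttall_window(L)
  for (b in seq_len(n_bands))
    ir[, b] <- kernel_from_amplitude(amp[, b], nfft, half, win)
  realized <- abs(stats::mvfft(rbind(ir, matrix(0, nfft - L, n_bands))))
  realized <- realized[seq_along(freq), , drop = FALSE]

  edges_lo <- c(0, cutoffs)
  edges_hi <- c(cutoffs, Inf)
  centers <- sqrt(edges_lo * edges_hi)
  centers[1] <- cutoffs[1] / sqrt(2)
  centers[n_bands] <- cutoffs[length(cutoffs)] * sqrt(2)

  structure(
    list(cutoffs = cutoffs, rolloff = rolloff, fs = fs,
         ir_duration = ir_duration, freq = freq, designed_amp = amp,
         ir = ir, realized_mag = realized, centers = centers,
         n_bands = n_bands),
    class = "band_filter_bank")
}

# Zero-phase kernel from a sampled amplitude response: hermitian spectrum ->
# IFFT (peak at sample 1, symmetric wrap) -> take L samples centered on the
# peak -> Nuttall window.
kernel_from_amplitude <- function(amp, nfft, half, win) {
  spec <- c(amp, rev(amp[2:(length(amp) - 1L)]))
  irf <- Re(stats::fft(spec, inverse = TRUE)) / nfft
  idx <- c((nfft - half + 1L):nfft, 1L:(half + 1L))
  irf[idx] * win
}

#' @export
print.band_filter_bank <- function(x, ...) {
  cat(sprintf("<band_filter_bank> %d bands, fs %g Hz, %d-sample Nuttall IRs\n",
              x$n_bands, x$fs, nrow(x$ir)))
  cat("  centers (Hz):", paste(signif(x$centers, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Apply one band filter to a waveform
#'
#' Linear convolution with the band's Nuttall-windowed kernel,
#' delay-compensated by the kernel's group delay so the output is
#' time-aligned with the input and has the same length.
#'
#' @param x Numeric waveform sampled at the bank's `fs`.
#' @param bank A [design_band_filters()] bank.
#' @param band Band index (1 = lowest).
#' @return Filtered waveform, same length as `x`.
#' @export
apply_band_filter <- function(x, bank, band) {
  stopifnot(inherits(bank, "band_filter_bank"))
  band <- as.integer(band)
  if (band < 1L || band > bank$n_bands) stop("band index out of range")
  conv_centered(as.numeric(x), bank$ir[, band])
}

#' Low-pass limit filter for broadband peaky speech
#'
#' Constructed from the penultimate octave band by setting the amplitude of
#' all frequencies below that band's high-pass roll-off to 1, yielding the
#' low-pass used to limit broadband peaky speech to 8 kHz (diotic) or
#' 11.36 kHz (dichotic) before the unaltered top band is added back.
#'
#' @param bank A [design_band_filters()] bank with at least 2 bands.
#' @return A single-band `band_filter_bank` holding the limit filter.
#' @export
broadband_limit_filter <- function(bank) {
  stopifnot(inherits(bank, "band_filter_bank"), bank$n_bands >= 2L)
  b <- bank$n_bands - 1L
  amp <- bank$designed_amp[, b]
  lo_edge <- if (b == 1L) 0 else bank$cutoffs[b - 1L]
  plateau_start <- lo_edge * 2^(bank$rolloff / 2)
  amp[bank$freq <= plateau_start] <- 1
  L <- nrow(bank$ir)
  nfft <- length(c(bank$freq, bank$freq[2:(length(bank$freq) - 1L)]))
  ir <- kernel_from_amplitude(amp, nfft, (L - 1L) %/% 2L, nuttall_window(L))
  out <- bank
  out$designed_amp <- matrix(amp, ncol = 1)
  out$ir <- matrix(ir, ncol = 1)
  realized <- abs(stats::fft(c(ir, numeric(nfft - L))))
  out$realized_mag <- matrix(realized[seq_along(bank$freq)], ncol = 1)
  out$centers <- bank$centers[b]
  out$n_bands <- 1L
  out
}

#' Export a filter bank as a frequency-response table
#'
#' @param bank A `band_filter_bank`.
#' @param realized Export the realized (post-windowing) magnitude instead of
#'   the designed amplitude.
#' @return A data frame with `freq_hz` and one magnitude column per band.
#' @export
bank_response_table <- function(bank, realized = FALSE) {
  stopifnot(inherits(bank, "band_filter_bank"))
  m <- if (realized) bank$realized_mag else bank$designed_amp
  out <- data.frame(freq_hz = bank$freq)
  for (b in seq_len(ncol(m)))
    out[[sprintf("band%d_mag", b)]] <- m[, b]
  out
}
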