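# Quality metrics: pairwise spectral coherence of regressor pulse trains
# (frequency range over which band responses are NOT frequency-specific),
# response SNR, SNR-per-minute and time-to-criterion.

# ---- spectral coherence ----------------------------------------------------

#' Pairwise spectral coherence of pulse trains
#'
#' Slices each regressor train into non-overlapping, rectangular-windowed
#' segments of `slice_dur` seconds and computes, for every pair of trains,
#' \deqn{C_{xy} = \frac{|E[F\{x_i\}^* F\{y_i\}]|}
#'   {\sqrt{E[F\{x_i\}^* F\{x_i\}]\, E[F\{y_i\}^* F\{y_i\}]}}}
#' with the expectation taken across slices. Coherence is 1 where two
#' trains carry locked phase (the shared voiced onsets/offsets make all
#' trains coherent at low frequencies) and drops toward the
#' \eqn{1/\sqrt{n_{slices}}} estimation floor where the shifted
#' fundamentals have drifted apart.
#'
#' @param trains List of numeric regressor vectors at `fs` (all the same
#'   length), or list of pulse-time vectors when `duration` is given (then
#'   converted through [pulses_to_regressor()]).
#' @param fs Sampling frequency of the regressors in Hz.
#' @param duration Total train duration in seconds, required when `trains`
#'   are pulse times.
#' @param slice_dur Slice duration in seconds (default 1; the frequency
#'   resolution is `1/slice_dur`).
#' @param max_freq Highest frequency bin retained in Hz (default 500).
#' @return An object of class `coherence_spectrum`: `freq` (Hz), `C`
#'   (pairs x bins matrix in \[0,1\]), `pairs` (data frame of train name
#'   pairs), `n_slices`, `slice_duration`.
#' @export
spectral_coherence <- function(trains, fs, duration = NULL, slice_dur = 1,
                               max_freq = 500) {
  stopifnot(is.list(trains), length(trains) >= 2L)
  nms <- names(trains) %||% paste0("train", seq_along(trains))
  if (!is.null(duration)) {
    n_samp <- as.integer(round(duration * fs))
    trains <- lapply(trains, pulses_to_regressor, n_samples = n_samp,
                     fs_eeg = fs)
  }
  len <- unique(vapply(trains, length, integer(1)))
  if (length(len) != 1L) stop("all trains must have equal length")
  n_per <- as.integer(round(slice_dur * fs))
  n_slices <- len %/% n_per
  if (n_slices < 2L) stop("fewer than 2 slices; provide longer trains")
  n_bins <- min(n_per %/% 2L, as.integer(floor(max_freq * slice_dur))) + 1L
  freq <- (seq_len(n_bins) - 1L) / slice_dur

  # FFT per slice, keeping only the low bins of interest.
  X <- lapply(trains, function(x) {
    m <- matrix(x[seq_len(n_slices * n_per)], nrow = n_per)
    sl <- stats::mvfft(m)          # bins x slices
    t(sl[seq_len(n_bins), , drop = FALSE])  # slices x bins
  })
  pxx <- lapply(X, function(x) colMeans(Re(x)^2 + Im(x)^2))

  pairs <- utils::combn(length(trains), 2)
  C <- matrix(0, ncol(pairs), n_bins)
  flags <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sxy <- colMeans(Conj(X[[a]]) * X[[b]])
    den <- sqrt(pxx[[a]] * pxx[[b]])
    cc <- numeric(n_bins)
    ok <- den > 0
    cc[ok] <- Mod(sxy[ok]) / den[ok]
    flags[p] <- any(!ok)
    C[p, ] <- pmin(cc, 1)
  }
  structure(
    list(freq = freq, C = C,
         pairs = data.frame(a = nms[pairs[1, ]], b = nms[pairs[2, ]]),
         n_slices = n_slices, slice_duration = slice_dur,
         zero_energy_flag = flags),
    class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d pair(s), %d slices of %g s, %g-%g Hz\n",
              nrow(x$C), x$n_slices, x$slice_duration, x$freq[1],
              x$freq[length(x$freq)]))
  invisible(x)
}

#' Coherence cutoff frequency
#'
#' Highest frequency at which any pairwise coherence exceeds `threshold`.
#' Above this cutoff the pulse trains are independent and evoked responses
#' are frequency-specific; below it a common response component is shared
#' across bands.
#'
#' The cutoff is a property of the coherence *curve*, so each pair's
#' spectrum is passed through a short running median (`median_bins`) before
#' thresholding: in frequency regions where only a handful of slices carry
#' power, the magnitude-coherence estimator is biased upward and isolated
#' single-bin exceedances appear by chance among the thousands of
#' (pair, bin) combinations; the median guard removes those while leaving
#' any contiguous exceedance region untouched. Set `median_bins = 1` for
#' the raw per-bin rule.
#'
#' @param spec A [spectral_coherence()] object.
#' @param threshold Coherence threshold (default 0.1).
#' @param median_bins Odd width of the running-median noise guard
#'   (default 5).
#' @return Cutoff frequency in Hz (0 if no bin exceeds the threshold).
#' @export
coherence_cutoff <- function(spec, threshold = 0.1, median_bins = 5L) {
  stopifnot(inherits(spec, "coherence_spectrum"), median_bins %% 2L == 1L)
  C <- spec$C
  if (median_bins > 1L && ncol(C) > median_bins) {
    C <- t(apply(C, 1, stats::runmed, k = median_bins,
                 endrule = "keep"))
  }
  above <- apply(C > threshold, 2, any)
  if (!any(above)) return(0)
  max(spec$freq[above])
}

# ---- SNR -------------------------------------------------------------------

#' Response SNR in dB
#'
#' Estimates \eqn{SNR_w = 10\log_{10}[(\sigma^2_{S+N} - \sigma^2_N) /
#' \sigma^2_N]}, where \eqn{\sigma^2_{S+N}} is the variance of the response
#' within `signal_window` and \eqn{\sigma^2_N} is the mean variance of
#' consecutive pre-stimulus baseline segments of the same length tiled
#' across `noise_window` (partial tail segments discarded). When the signal
#' window variance does not exceed the noise estimate, the SNR is `-Inf`
#' (no detectable response).
#'
#' @param w A `response_waveform`.
#' @param signal_window Length-2 window in ms (e.g. `c(0, 15)` for the ABR,
#'   `c(0, 30)` for ABR+MLR).
#' @param noise_window Length-2 pre-stimulus window in ms
#'   (default `c(-480, -20)`).
#' @param t_w Recording duration in seconds behind the waveform (optional;
#'   enables `snr60` and `t_0db` in the result).
#' @return An object of class `snr_estimate` with `snr_w` (dB),
#'   `var_signal_window`, `var_noise`, and when `t_w` is given `snr60` and
#'   `t_0db`.
#' @export
response_snr <- function(w, signal_window = c(0, 15),
                         noise_window = c(-480, -20), t_w = NULL) {
  stopifnot(inherits(w, "response_waveform"))
  sig_s <- signal_window / 1000
  noi_s <- noise_window / 1000
  if (w$lag[1] > noi_s[1] || w$lag[length(w$lag)] < sig_s[2])
    stop("response lag axis does not cover the requested windows")
  v_sig <- stats::var(w$w[lag_window_idx(w, sig_s)])
  seg_len <- diff(sig_s)
  n_seg <- floor(diff(noi_s) / seg_len)
  if (n_seg < 1L) stop("noise window shorter than the signal window")
  v_noise <- mean(vapply(seq_len(n_seg), function(k) {
    win <- noi_s[1] + c(k - 1, k) * seg_len
    stats::var(w$w[lag_window_idx(w, win)])
  }, numeric(1)))
  snr_w <- if (v_sig > v_noise)
    10 * log10((v_sig - v_noise) / v_noise) else -Inf
  out <- structure(
    list(snr_w = snr_w, var_signal_window = v_sig, var_noise = v_noise,
         signal_window = signal_window, noise_window = noise_window,
         t_w = t_w, snr60 = NULL, t_0db = NULL),
    class = "snr_estimate")
  if (!is.null(t_w) && is.finite(snr_w)) {
    out$snr60 <- snr_per_minute(snr_w, t_w)
    out$t_0db <- time_to_0db(out$snr60)
  }
  out
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("<snr_estimate> SNR_w = %.2f dB over %g-%g ms",
              x$snr_w, x$signal_window[1], x$signal_window[2]))
  if (!is.null(x$snr60))
    cat(sprintf("; SNR60 = %.2f dB; t(0 dB) = %.1f s", x$snr60, x$t_0db))
  cat("\n")
  invisible(x)
}

#' SNR normalized to one minute of recording
#'
#' \eqn{SNR_{60} = SNR_w + 10\log_{10}(60/t_w)}.
#'
#' @param snr_w Waveform SNR in dB.
#' @param t_w Recording duration in seconds.
#' @return SNR60 in dB.
#' @export
snr_per_minute <- function(snr_w, t_w) {
  stopifnot(t_w > 0)
  snr_w + 10 * log10(60 / t_w)
}

#' Acquisition time to reach 0 dB SNR
#'
#' \eqn{t_{0dB} = 60 \times 10^{-SNR_{60}/10}} seconds.
#'
#' @param snr60 SNR60 in dB (finite).
#' @return Time in seconds.
#' @export
time_to_0db <- function(snr60) {
  stopifnot(is.finite(snr60))
  60 * 10^(-snr60 / 10)
}

#' Cumulative proportion of subjects reaching criterion
#'
#' @param t_0db_values Per-subject times-to-criterion in seconds.
#' @param grid Evaluation times in seconds.
#' @return Data frame with `time_s` and `proportion` (monotone
#'   non-decreasing in \[0, 1\]).
#' @export
cumulative_proportion <- function(t_0db_values, grid) {
  stopifnot(length(t_0db_values) >= 1L)
  data.frame(time_s = grid,
             proportion = vapply(grid,
                                 function(g) mean(t_0db_values <= g),
                                 numeric(1)))
}
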