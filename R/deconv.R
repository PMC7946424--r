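# Response derivation: EEG preprocessing, pulse-train regressors,
# inverse-variance weighted frequency-domain deconvolution, causal filter
# presets, common-component estimation/subtraction and normalization.

# ---- EEG preprocessing -----------------------------------------------------

#' Preprocess raw EEG
#'
#' Causal first-order Butterworth high-pass at `hp_hz`, followed by 5-Hz
#' wide second-order IIR notch filters at the power-line fundamental and
#' its odd harmonics (60, 180, 300, 420 Hz by default). All filters are
#' causal so no response energy moves to negative lags.
#'
#' @param x Numeric vector, or a channels-in-rows matrix.
#' @param fs Sampling frequency in Hz (10000 nominal).
#' @param hp_hz High-pass cutoff in Hz (default 1).
#' @param notch_hz Notch center frequencies in Hz.
#' @param notch_width Notch -3 dB width in Hz (default 5).
#' @return Filtered data, same shape as `x`.
#' @export
preprocess_eeg <- function(x, fs = 10000, hp_hz = 1,
                           notch_hz = c(60, 180, 300, 420),
                           notch_width = 5) {
  if (is.matrix(x))
    return(t(apply(x, 1, preprocess_eeg, fs = fs, hp_hz = hp_hz,
                   notch_hz = notch_hz, notch_width = notch_width)))
  y <- butter_filter(as.numeric(x), hp_hz, fs, "high", 1L)
  for (f0 in notch_hz) y <- iir_notch(y, f0, notch_width, fs)
  y
}

# Second-order IIR notch biquad: zeros on the unit circle at +/- w0, poles
# just inside at radius R set by the -3 dB bandwidth.
iir_notch <- function(x, f0, width, fs) {
  w0 <- 2 * pi * f0 / fs
  bw <- 2 * pi * width / fs
  R <- 1 / (1 + tan(bw / 2))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * R * cos(w0), R^2)
  k <- sum(a) / sum(b)                    # unity gain at DC
  as.numeric(signal::filter(b * k, a, x))
}

# ---- regressors and epochs -------------------------------------------------

#' Convert pulse times to a unit-impulse regressor
#'
#' Each pulse time is scaled by `clock_ratio` (correcting small clock-rate
#' differences between the sound card and EEG system) and a unit impulse is
#' placed at the nearest EEG sample -- no fractional-amplitude temporal
#' splatter. Two pulses mapping to the same sample produce amplitude 2 with
#' a warning.
#'
#' @param times Pulse times in seconds, or a [pulse_train()].
#' @param n_samples Regressor length in samples (one epoch).
#' @param fs_eeg EEG sampling frequency in Hz (default 10000).
#' @param clock_ratio Sound-card/EEG clock ratio, near 1.
#' @return Numeric vector of length `n_samples`.
#' @export
pulses_to_regressor <- function(times, n_samples, fs_eeg = 10000,
                                clock_ratio = 1) {
  if (inherits(times, "pulse_train")) times <- times$times
  if (abs(clock_ratio - 1) >= 1e-3)
    stop("clock_ratio must be within 1e-3 of 1")
  n_samples <- as.integer(n_samples)
  x <- numeric(n_samples)
  if (!length(times)) return(x)
  idx <- round(as.numeric(times) * clock_ratio * fs_eeg) + 1L
  idx <- idx[idx >= 1L & idx <= n_samples]
  if (anyDuplicated(idx))
    warning("multiple pulses mapped to the same EEG sample")
  tab <- tabulate(idx, nbins = n_samples)
  x + tab
}

#' Epoched EEG recording
#'
#' @param y Numeric `n_epochs x n_samples` matrix of EEG in microvolts.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `epoched_recording` with per-epoch variances
#'   and inverse-variance weights.
#' @export
epoched_recording <- function(y, fs = 10000) {
  y <- as.matrix(y)
  v <- apply(y, 1, stats::var)
  structure(list(y = y, fs = fs, epoch_variances = v,
                 weights = epoch_weights(v)),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d epochs x %d samples (%.1f s at %g Hz)\n",
              nrow(x$y), ncol(x$y), ncol(x$y) / x$fs, x$fs))
  invisible(x)
}

#' Inverse-variance epoch weights
#'
#' Bayesian-like averaging weight for epoch i:
#' \eqn{b_i = (1/\sigma_i^2) / \sum_j (1/\sigma_j^2)}, replacing hard
#' artifact rejection. Variances are floored at `1e-12 * max` to guard
#' silent epochs; if all epochs are zero, uniform weights are returned with
#' a warning.
#'
#' @param v Numeric vector of per-epoch variances (or an
#'   `epoched_recording`).
#' @return Numeric weights summing to 1.
#' @export
epoch_weights <- function(v) {
  if (inherits(v, "epoched_recording")) v <- v$epoch_variances
  v <- as.numeric(v)
  if (any(v < 0)) stop("variances must be non-negative")
  if (max(v) == 0) {
    warning("all epochs have zero variance; using uniform weights")
    return(rep(1 / length(v), length(v)))
  }
  v <- pmax(v, 1e-12 * max(v))
  w <- (1 / v) / sum(1 / v)
  w
}

# ---- response waveform -----------------------------------------------------

new_response_waveform <- function(w, lag, fs, provenance = character()) {
  structure(list(w = as.numeric(w), lag = as.numeric(lag), fs = fs,
                 provenance = provenance),
            class = "response_waveform")
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf("<response_waveform> lags [%.3f, %.3f] s at %g Hz",
              x$lag[1], x$lag[length(x$lag)], x$fs))
  if (length(x$provenance))
    cat("; filters:", paste(x$provenance, collapse = " -> "))
  cat("\n")
  invisible(x)
}

#' Export a response waveform as a table
#'
#' @param w A `response_waveform`.
#' @return Data frame with `lag_ms` and `amplitude_uV`.
#' @export
response_table <- function(w) {
  stopifnot(inherits(w, "response_waveform"))
  data.frame(lag_ms = w$lag * 1000, amplitude_uV = w$w)
}

# Index range of a [start, end) lag window given in seconds.
lag_window_idx <- function(w, window_s) {
  which(w$lag >= window_s[1] & w$lag < window_s[2])
}

# ---- deconvolution ---------------------------------------------------------

#' Derive a response by weighted frequency-domain deconvolution
#'
#' Computes the impulse response of the system taking the stimulus
#' regressor to the EEG:
#' \deqn{w = F^{-1}\left\{\frac{\sum_i b_i F\{x_i\}^* F\{y_i\}}
#'   {\sum_i \frac{1}{n} F\{x_i\}^* F\{x_i\}}\right\}}
#' i.e. the cross-spectral density summed across inverse-variance weighted
#' epochs divided by the equal-weighted average power spectral density of
#' the regressor. No regularization is applied -- pulse-train regressors
#' are spectrally broadband. The circular result is shifted so lags run
#' from \eqn{-T/2} to \eqn{+T/2} and then trimmed to `lag_range`; any
#' filtering happens after the shift (see [filter_response()]).
#'
#' With unit-impulse regressors the response is in the units of the EEG
#' (microvolts). For half-wave rectified audio regressors, pass each epoch
#' as `list(pos = , neg = )` (see [halfwave_regressor()]): the positive and
#' the (signed) negative part are deconvolved as separate regressor
#' streams, each with the weighted-epochs formula, and the two responses
#' are combined with equal weight during averaging.
#'
#' @param regressors A single numeric regressor recycled across epochs, a
#'   list with one regressor per epoch, or a list of `list(pos, neg)`
#'   pairs.
#' @param epochs An [epoched_recording()] (or a plain matrix, microvolts).
#' @param fs Sampling frequency in Hz (taken from `epochs` if available).
#' @param weights Optional epoch weights; default inverse-variance from the
#'   recording.
#' @param lag_range Lag trim in seconds (default `c(-0.48, 0.5)`); `NULL`
#'   keeps the full circular lag axis.
#' @return A [response_table()]-compatible `response_waveform`.
#' @export
deconvolve <- function(regressors, epochs, fs = NULL, weights = NULL,
                       lag_range = c(-0.48, 0.5)) {
  if (inherits(epochs, "epoched_recording")) {
    y <- epochs$y
    fs <- fs %||% epochs$fs
    weights <- weights %||% epochs$weights
  } else {
    y <- as.matrix(epochs)
    if (is.null(fs)) stop("fs is required when epochs is a plain matrix")
    weights <- weights %||% epoch_weights(apply(y, 1, stats::var))
  }
  n_ep <- nrow(y)
  n <- ncol(y)
  xs <- normalize_regressors(regressors, n_ep, n)
  n_parts <- unique(vapply(xs, length, integer(1)))
  if (length(n_parts) != 1L)
    stop("all epochs must carry the same number of regressor parts")

  zero <- complex(real = numeric(n), imaginary = numeric(n))
  num <- rep(list(zero), n_parts)
  den <- rep(list(zero), n_parts)
  for (i in seq_len(n_ep)) {
    Yi <- stats::fft(y[i, ])
    for (j in seq_len(n_parts)) {
      Xi <- stats::fft(xs[[i]][[j]])
      num[[j]] <- num[[j]] + weights[i] * Conj(Xi) * Yi
      den[[j]] <- den[[j]] + Conj(Xi) * Xi / n_ep
    }
  }
  w_freq <- zero
  for (j in seq_len(n_parts)) {
    if (mean(Re(den[[j]])) < .Machine$double.eps * n)
      stop("regressor has near-zero energy; deconvolution would blow up")
    w_freq <- w_freq + num[[j]] / den[[j]] / n_parts
  }
  w_full <- Re(stats::fft(w_freq, inverse = TRUE)) / n
  # circular lags: [0, T/2) at the start, [-T/2, 0) at the end; shift so
  # the lag axis runs -T/2 .. +T/2 with lag 0 at the original first sample
  half_up <- (n + 1L) %/% 2L
  w_shift <- c(w_full[(half_up + 1L):n], w_full[1:half_up])
  lag <- (seq_len(n) - 1L - (n - half_up)) / fs
  out <- new_response_waveform(w_shift, lag, fs)
  if (!is.null(lag_range)) {
    keep <- out$lag >= lag_range[1] & out$lag <= lag_range[2]
    out$w <- out$w[keep]
    out$lag <- out$lag[keep]
  }
  out
}

# Accepts: numeric vector (recycled), list of vectors, or list of
# list(pos, neg); returns list (per epoch) of lists of regressor parts.
# Rectified pairs become (pos, -neg): the negative lobe keeps its sign so
# that both streams see the system with the same polarity.
normalize_regressors <- function(regressors, n_ep, n) {
  as_parts <- function(r) {
    if (is.numeric(r)) {
      stopifnot(length(r) == n)
      list(as.numeric(r))
    } else if (is.list(r) && !is.null(r$pos)) {
      stopifnot(length(r$pos) == n, length(r$neg) == n)
      list(as.numeric(r$pos), -as.numeric(r$neg))
    } else stop("unrecognized regressor format")
  }
  if (is.numeric(regressors) ||
      (is.list(regressors) && !is.null(regressors$pos))) {
    rep(list(as_parts(regressors)), n_ep)
  } else {
    stopifnot(length(regressors) == n_ep)
    lapply(regressors, as_parts)
  }
}

#' Split a waveform into half-wave rectified regressor parts
#'
#' @param x Numeric waveform (audio resampled to the EEG rate).
#' @return A list with `pos` and `neg` such that `pos - neg = x`.
#' @export
halfwave_regressor <- function(x) {
  x <- as.numeric(x)
  list(pos = pmax(x, 0), neg = -pmin(x, 0), kind = "rect")
}

# ---- response filtering ----------------------------------------------------

FILTER_PRESETS <- list(
  abr_mlr = "bp30-2000hz_o1",
  abr = c("bp30-2000hz_o1", "hp150hz_o1"),
  early_abr = c("bp30-2000hz_o1", "hp200hz_o2"),
  full_range = c("hp1hz_o1", "lp2000hz_o1")
)

#' Filter a response waveform with a causal preset
#'
#' Presets follow the derivation chain used for speech-evoked subcortical
#' responses: `abr_mlr` = 30--2000 Hz band-pass (first-order causal
#' Butterworth); `abr` adds a 150 Hz first-order high-pass to sharpen waves
#' I and III; `early_abr` adds a more aggressive 200 Hz second-order
#' high-pass that also suppresses the broad pre-stimulus nonlinearity
#' component; `full_range` is a 1 Hz high-pass plus 2000 Hz low-pass. All
#' filters are causal, so no late response energy leaks into earlier lags.
#' The applied chain is appended to the waveform's provenance; re-applying
#' an identical chain is a warning no-op.
#'
#' @param w A `response_waveform` from [deconvolve()].
#' @param preset One of `"abr_mlr"`, `"abr"`, `"early_abr"`,
#'   `"full_range"`.
#' @return The filtered `response_waveform`.
#' @export
filter_response <- function(w, preset = c("abr_mlr", "abr", "early_abr",
                                          "full_range")) {
  stopifnot(inherits(w, "response_waveform"))
  preset <- match.arg(preset)
  chain <- FILTER_PRESETS[[preset]]
  if (length(w$provenance) &&
      identical(utils::tail(w$provenance, length(chain)), chain)) {
    warning("response already filtered with this preset; returning unchanged")
    return(w)
  }
  x <- w$w
  fs <- w$fs
  for (step in chain) {
    x <- switch(step,
      "bp30-2000hz_o1" = {
        if (2000 < fs / 2) {
          bf <- signal::butter(1, c(30, 2000) / (fs / 2), type = "pass")
          as.numeric(signal::filter(bf, x))
        } else {
          # low-rate responses already band-limited below the 2000 Hz edge
          butter_filter(x, 30, fs, "high", 1L)
        }
      },
      "hp150hz_o1" = butter_filter(x, 150, fs, "high", 1L),
      "hp200hz_o2" = butter_filter(x, 200, fs, "high", 2L),
      "hp1hz_o1" = butter_filter(x, 1, fs, "high", 1L),
      "lp2000hz_o1" = if (2000 < fs / 2)
        butter_filter(x, 2000, fs, "low", 1L) else x,
      stop("unknown filter step"))
  }
  new_response_waveform(x, w$lag, fs, c(w$provenance, chain))
}

# ---- common component ------------------------------------------------------

#' Common response component from fake pulse trains
#'
#' Deconvolves the same EEG against each "fake" pulse train (trains created
#' during multiband stimulus design but never synthesized into audio) and
#' averages the results with equal weight. Because the fake trains share the
#' low-frequency coherence of the true trains but none of their band
#' content, this average isolates the response component common to all
#' bands.
#'
#' @param epochs An [epoched_recording()].
#' @param fake_regressors List over fake trains; each element is a
#'   regressor in any form [deconvolve()] accepts (single vector recycled
#'   across epochs, or a per-epoch list).
#' @param true_regressors Optional list of true regressors (same forms); a
#'   fake train identical to a true one is rejected.
#' @param ... Passed to [deconvolve()].
#' @return The average `response_waveform` across fake trains.
#' @export
common_component <- function(epochs, fake_regressors,
                             true_regressors = NULL, ...) {
  if (length(fake_regressors) < 2L)
    stop("at least 2 fake pulse trains are required")
  if (!is.null(true_regressors)) {
    for (fk in fake_regressors) for (tr in true_regressors) {
      if (isTRUE(all.equal(fk, tr, check.attributes = FALSE)))
        stop("a fake pulse train is identical to a true train")
    }
  }
  resp <- lapply(fake_regressors, deconvolve, epochs = epochs, ...)
  w <- Reduce(`+`, lapply(resp, `[[`, "w")) / length(resp)
  new_response_waveform(w, resp[[1]]$lag, resp[[1]]$fs,
                        resp[[1]]$provenance)
}

#' Subtract the common component from band responses
#'
#' @param band_responses List of `response_waveform`s (one per band).
#' @param common The [common_component()] waveform; must share the lag axis
#'   and filter provenance of the band responses.
#' @return List of frequency-specific `response_waveform`s (provenance
#'   marked `"common-subtracted"`).
#' @export
subtract_common <- function(band_responses, common) {
  stopifnot(inherits(common, "response_waveform"))
  lapply(band_responses, function(b) {
    stopifnot(inherits(b, "response_waveform"))
    if (length(b$lag) != length(common$lag) ||
        max(abs(b$lag - common$lag)) > 1e-12)
      stop("band response and common component lag axes differ")
    if (!identical(b$provenance, common$provenance))
      stop("band response and common component filter provenance differ")
    new_response_waveform(b$w - common$w, b$lag, b$fs,
                          c(b$provenance, "common-subtracted"))
  })
}

# ---- normalization ---------------------------------------------------------

#' Normalization factor between continuous-regressor and pulse responses
#'
#' Responses derived with a continuous (half-wave rectified audio)
#' regressor are not in microvolts; to compare them with pulse-train
#' responses a factor \eqn{g = \bar\sigma_u / \bar\sigma_p} is computed,
#' where \eqn{\sigma_{u,i}} and \eqn{\sigma_{p,i}} are the standard
#' deviations of subject i's unaltered-speech and peaky-speech responses
#' within `window`. The unaltered-speech responses are then multiplied
#' by `g` (set `direction = "divide"` to apply it the other way).
#'
#' @param responses_unaltered,responses_peaky Paired lists of
#'   `response_waveform`s (one per subject).
#' @param window Length-2 window in ms (default `c(0, 20)`).
#' @return An object of class `scale_factor` with `g` and the per-subject
#'   SD pairs.
#' @export
normalization_factor <- function(responses_unaltered, responses_peaky,
                                 window = c(0, 20)) {
  stopifnot(length(responses_unaltered) == length(responses_peaky),
            length(responses_unaltered) >= 1L)
  win_s <- window / 1000
  sd_in_win <- function(w) {
    idx <- lag_window_idx(w, win_s)
    stats::sd(w$w[idx])
  }
  s_u <- vapply(responses_unaltered, sd_in_win, numeric(1))
  s_p <- vapply(responses_peaky, sd_in_win, numeric(1))
  if (mean(s_p) == 0) stop("peaky responses have zero SD in the window")
  structure(list(g = mean(s_u) / mean(s_p), window_ms = window,
                 per_subject_sds = data.frame(sd_unaltered = s_u,
                                              sd_peaky = s_p)),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> g = %.4g over %g-%g ms (%d subjects)\n",
              x$g, x$window_ms[1], x$window_ms[2],
              nrow(x$per_subject_sds)))
  invisible(x)
}

#' Apply a normalization factor to responses
#'
#' @param responses List of `response_waveform`s (or a single one).
#' @param g A `scale_factor` or bare numeric.
#' @param direction `"multiply"` (default, as applied to unaltered-speech
#'   responses) or `"divide"`.
#' @return Scaled responses of the same shape.
#' @export
apply_normalization <- function(responses, g,
                                direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  gval <- if (inherits(g, "scale_factor")) g$g else as.numeric(g)
  if (direction == "divide") gval <- 1 / gval
  scale1 <- function(w) {
    w$w <- w$w * gval
    w$provenance <- c(w$provenance, sprintf("scaled_x%.4g", gval))
    w
  }
  if (inherits(responses, "response_waveform")) scale1(responses)
  else lapply(responses, scale1)
}
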