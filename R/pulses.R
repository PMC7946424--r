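# Glottal pulse trains: smoothing, voiced segmentation, and the
# voiced/unvoiced mixer function used to crossfade re-synthesized and
# unaltered speech.

#' Glottal pulse train
#'
#' Container for a sequence of glottal pulse times extracted from (or
#' generated for) a speech waveform. Pulse times are in seconds and must be
#' strictly increasing; `f0_bounds` records the narrator's admissible pitch
#' range (60--350 Hz for a typical male narrator, 90--500 Hz for a female
#' narrator).
#'
#' @param times Numeric vector of pulse times in seconds, strictly
#'   increasing.
#' @param fs_audio Audio sampling frequency in Hz.
#' @param duration Total duration of the underlying audio in seconds.
#'   Defaults to the last pulse time.
#' @param f0_bounds Length-2 numeric, admissible fundamental frequency range
#'   in Hz.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(times, fs_audio = 44100, duration = NULL,
                        f0_bounds = c(60, 350)) {
  times <- as.numeric(times)
  if (length(times) && is.unsorted(times, strictly = TRUE))
    stop("pulse times must be strictly increasing")
  if (length(times) && times[1] < 0)
    stop("pulse times must be non-negative")
  duration <- duration %||% if (length(times)) times[length(times)] else 0
  if (length(times) && times[length(times)] > duration)
    stop("pulse times exceed the stated duration")
  structure(
    list(times = times, fs_audio = fs_audio, duration = duration,
         f0_bounds = as.numeric(f0_bounds)),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses over %.2f s (%.1f pulses/s), fs %g Hz\n",
              length(x$times), x$duration,
              if (x$duration > 0) length(x$times) / x$duration else 0,
              x$fs_audio))
  invisible(x)
}

#' Smooth glottal pulse times
#'
#' Applies 10 iterations of local averaging to a pulse-time sequence: pulse
#' \eqn{p_i} is replaced by the mean of \eqn{p_{i-1}, p_i, p_{i+1}} whenever
#' its two adjacent inter-pulse intervals agree within a factor of 1.6, i.e.
#' \eqn{|\log_2(\Delta_1/\Delta_2)| < \log_2 1.6}. Pulses at octave-jump
#' pitch-tracking errors (interval ratio above 1.6) are left untouched, as
#' are the first and last pulses. Each pass updates all pulses from the
#' previous pass's values, so the result does not depend on sweep order.
#'
#' @param times Numeric vector of pulse times in seconds, strictly
#'   increasing, or a [pulse_train].
#' @param n_iter Number of smoothing passes (default 10).
#' @param max_ratio Maximum adjacent-interval ratio for a pulse to be
#'   smoothed (default 1.6).
#' @return Smoothed pulse times (same type as the input).
#' @export
smooth_pulse_times <- function(times, n_iter = 10L, max_ratio = 1.6) {
  if (inherits(times, "pulse_train")) {
    out <- times
    out$times <- smooth_pulse_times(times$times, n_iter, max_ratio)
    return(out)
  }
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("pulse times must be strictly increasing")
  n <- length(times)
  if (n < 3L) return(times)
  thr <- log2(max_ratio)
  for (pass in seq_len(n_iter)) {
    d1 <- times[2:(n - 1)] - times[1:(n - 2)]
    d2 <- times[3:n] - times[2:(n - 1)]
    ok <- abs(log2(d1 / d2)) < thr
    mid <- (times[1:(n - 2)] + times[2:(n - 1)] + times[3:n]) / 3
    new_times <- times
    new_times[2:(n - 1)][ok] <- mid[ok]
    times <- new_times
  }
  times
}

#' Segment pulse times into voiced sections
#'
#' Pulses whose inter-pulse interval does not exceed `max_gap` (17 ms, the
#' period of a 60 Hz fundamental, the lowest pitch expected in natural
#' speech) are grouped into maximal voiced segments. A longer gap is treated
#' as a break between voiced sections. Isolated pulses form degenerate
#' single-pulse segments.
#'
#' @param times Numeric vector of pulse times in seconds (strictly
#'   increasing) or a [pulse_train].
#' @param max_gap Largest inter-pulse interval in seconds still considered
#'   voiced (default 0.017).
#' @return An object of class `voiced_segmentation`: a list with a
#'   `segments` data frame (`start`, `end`, `i_first`, `i_last` -- the
#'   first/last pulse index of each segment) and the pulse `times`.
#' @export
segment_voiced <- function(times, max_gap = 0.017) {
  if (inherits(times, "pulse_train")) times <- times$times
  times <- as.numeric(times)
  if (length(times) && is.unsorted(times, strictly = TRUE))
    stop("pulse times must be strictly increasing")
  if (!length(times)) {
    seg <- data.frame(start = numeric(0), end = numeric(0),
                      i_first = integer(0), i_last = integer(0))
    return(structure(list(segments = seg, times = times, max_gap = max_gap),
                     class = "voiced_segmentation"))
  }
  breaks <- which(diff(times) > max_gap)
  i_first <- c(1L, breaks + 1L)
  i_last <- c(breaks, length(times))
  seg <- data.frame(start = times[i_first], end = times[i_last],
                    i_first = i_first, i_last = i_last)
  structure(list(segments = seg, times = times, max_gap = max_gap),
            class = "voiced_segmentation")
}

#' @export
print.voiced_segmentation <- function(x, ...) {
  cat(sprintf("<voiced_segmentation> %d segments, %d pulses\n",
              nrow(x$segments), length(x$times)))
  invisible(x)
}

#' Build the voiced/unvoiced mixer function
#'
#' The mixer is 1 in unvoiced regions and 0 strictly inside voiced segments;
#' it later crossfades unaltered speech (`mixer`) with re-synthesized peaky
#' speech (`1 - mixer`). Binary transitions are smoothed with half
#' raised-cosine ramps spanning exactly the interval between the first and
#' second pulses (fade toward voiced) and between the last two pulses (fade
#' back to unvoiced) of each segment. A lone pulse gets a short fixed fade
#' (`lone_fade`) on each side to avoid clicks.
#'
#' @param seg A `voiced_segmentation` from [segment_voiced()].
#' @param fs Sampling frequency of the mixer grid in Hz.
#' @param n_samples Number of samples of the mixer vector.
#' @param lone_fade Fade duration in seconds used on each side of a
#'   single-pulse segment (default 0.005).
#' @return Numeric vector of length `n_samples` with values in \[0, 1\].
#' @export
build_mixer <- function(seg, fs, n_samples, lone_fade = 0.005) {
  stopifnot(inherits(seg, "voiced_segmentation"))
  if (fs <= 0) stop("fs must be positive")
  n_samples <- as.integer(n_samples)
  mixer <- rep(1, n_samples)
  t_grid <- (seq_len(n_samples) - 1L) / fs
  segs <- seg$segments
  for (s in seq_len(nrow(segs))) {
    idx <- segs$i_first[s]:segs$i_last[s]
    p <- seg$times[idx]
    if (length(p) == 1L) {
      down <- c(max(p - lone_fade, 0), p)
      up <- c(p, p + lone_fade)
    } else {
      down <- p[1:2]                       # first -> second pulse: 1 -> 0
      up <- p[c(length(p) - 1L, length(p))] # penultimate -> last: 0 -> 1
    }
    lo <- max(1L, round(down[1] * fs) + 1L)
    hi <- min(n_samples, round(up[2] * fs) + 1L)
    if (lo > hi) next
    tt <- t_grid[lo:hi]
    ramp_down <- ifelse(tt <= down[1], 1,
                 ifelse(tt >= down[2], 0,
                        0.5 * (1 + cos(pi * (tt - down[1]) / diff(down)))))
    ramp_up <- ifelse(tt <= up[1], 0,
               ifelse(tt >= up[2], 1,
                      0.5 * (1 - cos(pi * (tt - up[1]) / diff(up)))))
    # In a >=3 pulse segment the ramps do not overlap and the interior is 0;
    # in 1-2 pulse segments the pointwise max keeps the fade continuous.
    mixer[lo:hi] <- pmin(mixer[lo:hi], pmax(ramp_down, ramp_up))
  }
  mixer
}
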