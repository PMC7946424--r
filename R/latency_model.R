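# Power-law model of wave peak latency versus band center frequency:
# tau(f) = a + b * f^(-d), with a = synaptic delay (0.8 ms) + the subject's
# wave I-V inter-wave interval, fit in the log-log domain.

#' Fit the latency power law
#'
#' Fits \eqn{\tau(f) = a + b f^{-d}} where f is the band center frequency
#' in kHz (normalized to 1 kHz) and \eqn{a = \tau_{synaptic} + \tau_{I-V}}
#' is fixed per subject from that subject's wave I--V interval (with
#' \eqn{\tau_{synaptic} = 0.8} ms); subjects without an identifiable wave I
#' fall back to the group mean I--V interval. The fit is linear in the
#' log--log domain, \eqn{\log_{10}(\tau - a) = \log_{10} b - d \log_{10} f},
#' with \eqn{b = 10^{intercept}} and \eqn{d = -slope}; standard errors are
#' propagated from the linear fit. Observations with \eqn{\tau \le a} are
#' excluded with a message. Set `per_subject = TRUE` for a two-stage fit
#' (per-subject lines, then group mean and SE of the parameters).
#'
#' @param obs Data frame with columns `subject`, `band_center_khz`,
#'   `latency_ms`, and optionally `iv_ms` (wave I--V interval per subject,
#'   `NA` allowed).
#' @param tau_synaptic Synaptic delay in ms (default 0.8).
#' @param group_mean_iv Fallback I--V interval in ms for subjects with
#'   missing `iv_ms`; defaults to the mean of the available ones.
#' @param per_subject Two-stage per-subject fit instead of the pooled
#'   fixed-effects fit.
#' @return An object of class `power_law_fit` with `a` (mean across fitted
#'   subjects, ms), `b` (ms), `d`, `se_b`, `se_d`, `n_obs`, `n_excluded`
#'   and the underlying `lm` fit (pooled mode).
#' @export
fit_power_law <- function(obs, tau_synaptic = 0.8, group_mean_iv = NULL,
                          per_subject = FALSE) {
  stopifnot(is.data.frame(obs),
            all(c("subject", "band_center_khz", "latency_ms") %in%
                names(obs)))
  iv <- if ("iv_ms" %in% names(obs)) obs$iv_ms else rep(NA_real_, nrow(obs))
  group_mean_iv <- group_mean_iv %||%
    (if (any(!is.na(iv))) mean(iv[!is.na(iv)]) else
       stop("no I-V intervals available and no group_mean_iv fallback"))
  iv[is.na(iv)] <- group_mean_iv
  a <- tau_synaptic + iv
  keep <- obs$latency_ms > a
  if (!all(keep))
    message(sum(!keep), " observation(s) with latency <= a excluded")
  df <- data.frame(subject = obs$subject[keep],
                   f = obs$band_center_khz[keep],
                   tau = obs$latency_ms[keep], a = a[keep])
  if (length(unique(df$f)) < 2L)
    stop("at least 2 distinct band center frequencies are required")
  df$ly <- log10(df$tau - df$a)
  df$lf <- log10(df$f)

  if (!per_subject) {
    fit <- stats::lm(ly ~ lf, data = df)
    co <- summary(fit)$coefficients
    b <- 10^co[1, 1]
    out <- list(a = mean(df$a), b = b, d = -co[2, 1],
                se_b = log(10) * b * co[1, 2], se_d = co[2, 2],
                n_obs = nrow(df), n_excluded = sum(!keep),
                fit = fit, per_subject = FALSE)
  } else {
    subj <- split(df, df$subject)
    bd <- t(vapply(subj, function(s) {
      if (length(unique(s$f)) < 2L) return(c(NA_real_, NA_real_))
      co <- stats::coef(stats::lm(ly ~ lf, data = s))
      c(10^co[1], -co[2])
    }, numeric(2)))
    bd <- bd[stats::complete.cases(bd), , drop = FALSE]
    if (nrow(bd) < 1L) stop("no subject had enough bands for a fit")
    out <- list(a = mean(df$a), b = mean(bd[, 1]), d = mean(bd[, 2]),
                se_b = stats::sd(bd[, 1]) / sqrt(nrow(bd)),
                se_d = stats::sd(bd[, 2]) / sqrt(nrow(bd)),
                n_obs = nrow(df), n_excluded = sum(!keep),
                fit = NULL, per_subject = TRUE)
  }
  structure(out, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> tau(f) = %.2f + %.2f * f^(-%.3f) ms (b SE %.2f, d SE %.3f, n = %d)\n",
    x$a, x$b, x$d, x$se_b, x$se_d, x$n_obs))
  invisible(x)
}

#' Predict latency from a power-law fit
#'
#' \eqn{\tau(f) = a + b f^{-d}}, f in kHz normalized to 1 kHz.
#'
#' @param fit A `power_law_fit` (or a list with `a`, `b`, `d`).
#' @param f Band center frequencies in kHz.
#' @return Predicted latencies in ms.
#' @export
predict_latency <- function(fit, f) {
  stopifnot(all(f > 0))
  fit$a + fit$b * f^(-fit$d)
}

#' Pick a wave peak within a canonical latency window
#'
#' Convenience helper that returns the lag of the largest local maximum of
#' a response waveform within `window` (default 5--13 ms, the canonical
#' wave V range). Peak picking for real data is normally done by eye; this
#' helper only automates the synthetic case.
#'
#' @param w A `response_waveform`.
#' @param window Length-2 search window in ms.
#' @return Peak latency in ms (`NA` if no local maximum exists).
#' @export
pick_peak_latency <- function(w, window = c(5, 13)) {
  stopifnot(inherits(w, "response_waveform"))
  idx <- lag_window_idx(w, window / 1000)
  if (length(idx) < 3L) return(NA_real_)
  x <- w$w[idx]
  loc <- which(diff(sign(diff(x))) < 0) + 1L   # tolerate plateau tops
  if (!length(loc)) return(NA_real_)
  best <- loc[which.max(x[loc])]
  w$lag[idx[best]] * 1000
}
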