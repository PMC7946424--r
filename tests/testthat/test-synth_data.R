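test_that("narrator specs encode the stated statistics and reject infeasible ones", {
  m <- narrator_spec("male")
  expect_equal(m$voiced_f0_mean, 115.1)
  expect_equal(m$f0_bounds, c(60, 350))
  expect_equal(m$target_rate, 69.1)
  f <- narrator_spec("female")
  expect_equal(f$voiced_f0_mean, 198.1)
  expect_equal(f$f0_bounds, c(90, 500))
  expect_equal(f$target_rate, 110.8)
  # a rate above the voiced fundamental cannot be reached
  expect_error(narrator_spec("male", target_rate = 120), "infeasible")
  expect_error(narrator_spec("male", f0_bounds = c(110, 120)), "2 SD")
})

test_that("speech-like generation is seeded-deterministic and self-consistent", {
  spec <- narrator_spec("male")
  a <- synth_speech_like(spec, 4, seed = 42)
  b <- synth_speech_like(spec, 4, seed = 42)
  expect_identical(a$audio, b$audio)
  expect_identical(a$pulses$times, b$pulses$times)
  expect_false(identical(a$pulses$times,
                         synth_speech_like(spec, 4, seed = 43,
                                           audio = FALSE)$pulses$times))
  # returned pulses re-segment into exactly the generated voiced intervals
  seg <- segment_voiced(a$pulses$times)
  expect_identical(nrow(seg$segments), nrow(a$voiced_intervals))
  expect_equal(seg$segments$start, a$voiced_intervals$start,
               tolerance = 1e-6)
  # audio on the storage scale
  expect_equal(sqrt(mean(a$audio^2)), 0.01, tolerance = 1e-9)
  expect_error(synth_speech_like(spec, 0.5, seed = 1), "at least 1")
})

test_that("realized pulse rates match the narrator targets across segments", {
  for (narr in c("male", "female")) {
    spec <- narrator_spec(narr)
    rates <- vapply(1:10, function(s) {
      sp <- synth_speech_like(spec, 64, seed = 7000 + s, audio = FALSE)
      length(sp$pulses$times) / 64
    }, numeric(1))
    expect_lt(abs(mean(rates) - spec$target_rate), spec$rate_sd)
    # and the voiced-interior rate sits near the narrator fundamental
    sp <- synth_speech_like(spec, 64, seed = 7011, audio = FALSE)
    d <- diff(sp$pulses$times)
    f0_hat <- mean(1 / d[d < 0.017])
    expect_lt(abs(f0_hat - spec$voiced_f0_mean),
              0.15 * spec$voiced_f0_mean)
  }
})

test_that("the tri-peak kernel follows its construction contract", {
  k <- make_abr_kernel()
  expect_equal(max(abs(k$kernel)), 1)
  # zero before wave I on the positive side and across all negative lags
  expect_identical(max(abs(k$kernel[k$lag < 0.0016])), 0)
  # dominant peak at the wave V latency
  expect_equal(k$lag[which.max(k$kernel)] * 1000, 7.22, tolerance = 0.1)
  expect_error(make_abr_kernel(wave_latencies_ms = c(1.0, 5, 7)), "1.6")
  expect_error(make_abr_kernel(wave_latencies_ms = c(5, 3, 7)),
               "increasing")
})

test_that("simulated EEG inverts exactly without noise and is seeded", {
  spec <- narrator_spec("male")
  kern <- make_abr_kernel()
  sp <- synth_speech_like(spec, 8, seed = 77, audio = FALSE)
  reg <- pulses_to_regressor(sp$pulses$times, 8 * 10000, 10000)
  rec <- simulate_eeg(reg, kern, n_epochs = 2, snr_db = Inf, seed = 3)
  w <- deconvolve(reg, rec)
  sel <- w$lag >= 0 & w$lag < 0.016
  ksel <- kern$lag >= 0 & kern$lag < 0.016
  expect_gt(stats::cor(w$w[sel], kern$kernel[ksel]), 0.999)
  # determinism
  rec2 <- simulate_eeg(reg, kern, n_epochs = 2, snr_db = Inf, seed = 3)
  expect_identical(rec$y, rec2$y)
  # line noise shows up at the requested frequencies
  recl <- simulate_eeg(reg, kern, n_epochs = 1, snr_db = -10,
                       line_freqs = 60, seed = 4)
  sp60 <- abs(stats::fft(recl$y[1, ]))
  bin60 <- 60 * 8 + 1
  expect_gt(sp60[bin60], 5 * stats::median(sp60[(bin60 + 20):(bin60 + 200)]))
})

test_that("noise-only simulation mostly fails the SNR criterion", {
  spec <- narrator_spec("male")
  kern <- make_abr_kernel()
  sp <- synth_speech_like(spec, 8, seed = 78, audio = FALSE)
  reg <- pulses_to_regressor(sp$pulses$times, 8 * 10000, 10000)
  sentinel <- vapply(1:16, function(s) {
    rec <- simulate_eeg(reg, kern, n_epochs = 2, snr_db = -20,
                        kernel_gain = 0, seed = 100 + s)
    w <- filter_response(deconvolve(reg, rec), "abr_mlr")
    !is.finite(response_snr(w, signal_window = c(0, 15))$snr_w)
  }, logical(1))
  # no detectable response in a large share of pure-noise runs (the
  # sentinel fires roughly half the time; well above it with real signal)
  expect_gte(mean(sentinel), 0.3)
})
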