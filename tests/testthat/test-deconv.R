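test_that("EEG preprocessing is a causal high-pass plus line notches", {
  fs <- 10000
  n <- 5 * fs
  t <- (0:(n - 1)) / fs
  # DC decays toward zero in steady state
  y_dc <- preprocess_eeg(rep(1, n), fs)
  expect_lt(max(abs(y_dc[(n - fs):n])), 0.01)
  # 60 Hz attenuated by >= 20 dB, 500 Hz passed within 1 dB
  ss <- (2 * fs):n
  g60 <- sqrt(mean(preprocess_eeg(sin(2 * pi * 60 * t), fs)[ss]^2) / 0.5)
  g500 <- sqrt(mean(preprocess_eeg(sin(2 * pi * 500 * t), fs)[ss]^2) / 0.5)
  expect_lt(20 * log10(g60), -20)
  expect_lt(abs(20 * log10(g500)), 1)
  # causality: an impulse response is zero before the impulse
  imp <- numeric(fs); imp[100] <- 1
  h <- preprocess_eeg(imp, fs)
  expect_identical(max(abs(h[1:99])), 0)
  # matrix input: channels in rows
  m <- preprocess_eeg(rbind(rep(1, n), sin(2 * pi * 500 * t)), fs)
  expect_equal(dim(m), c(2, n))
})

test_that("pulse times map to nearest-sample unit impulses", {
  r <- pulses_to_regressor(1.00004, 20000, fs_eeg = 10000)
  expect_identical(which(r == 1) - 1L, 10000L)      # 0-based sample 10000
  r2 <- pulses_to_regressor(10, 200000, fs_eeg = 10000,
                            clock_ratio = 1.0001)
  expect_identical(which(r2 == 1) - 1L, 100010L)
  expect_identical(pulses_to_regressor(numeric(0), 100), numeric(100))
  expect_true(all(pulses_to_regressor(c(0.01, 0.02), 1000, 10000) %in%
                    c(0, 1)))
  expect_warning(r3 <- pulses_to_regressor(c(0.5, 0.50001), 10000, 10000),
                 "same")
  expect_identical(max(r3), 2)
  expect_error(pulses_to_regressor(1, 100, clock_ratio = 1.01), "1e-3")
})

test_that("epoch weights are normalized inverse variances", {
  expect_equal(epoch_weights(rep(2, 5)), rep(0.2, 5))
  expect_equal(epoch_weights(c(1, 3)), c(0.75, 0.25))
  expect_equal(epoch_weights(7), 1)
  expect_warning(w <- epoch_weights(c(0, 0, 0)), "uniform")
  expect_equal(w, rep(1 / 3, 3))
  # silent-epoch guard: a zero variance cannot swallow all the weight
  w2 <- epoch_weights(c(0, 1, 1))
  expect_lt(w2[1], 1)
  expect_equal(sum(w2), 1)
})

test_that("deconvolution inverts trivial systems exactly", {
  fs <- 100
  n <- 64
  x <- numeric(n); x[c(4, 20, 41)] <- 1
  # y = x -> unit impulse at lag 0
  w <- deconvolve(x, matrix(x, 1), fs = fs, lag_range = NULL)
  expect_equal(w$w[w$lag == 0], 1, tolerance = 1e-12)
  expect_lt(max(abs(w$w[w$lag != 0])), 1e-12)
  # y = 2x delayed k samples -> 2*delta(lag k/fs)
  k <- 5L
  y <- 2 * c(numeric(k), x[1:(n - k)])
  w2 <- deconvolve(x, matrix(y, 1), fs = fs, lag_range = NULL)
  expect_equal(w2$w[w2$lag == k / fs], 2, tolerance = 1e-12)
  expect_lt(max(abs(w2$w[w2$lag != k / fs])), 1e-12)
  # zero-energy regressor rejected
  expect_error(deconvolve(numeric(n), matrix(y, 1), fs = fs), "energy")
})

test_that("frequency-domain estimator matches circulant least squares", {
  withr::with_seed(2, {
    for (n in c(1024, 4096)) {
      x <- stats::rnorm(n)
      h <- stats::dnorm(seq(-3, 3, length.out = 21))
      idx <- outer(seq_len(n), 0:(n - 1),
                   function(i, k) ((i - k - 1) %% n) + 1)
      X <- matrix(x[idx], n, n)
      y <- as.numeric(X %*% c(h, numeric(n - 21)))
      w_ls <- as.numeric(solve(crossprod(X), crossprod(X, y)))
      w <- deconvolve(x, matrix(y, 1), fs = 1000, lag_range = NULL)
      w_circ <- c(w$w[w$lag >= 0], w$w[w$lag < 0])  # back to circular order
      expect_lt(max(abs(w_circ - w_ls)) / max(abs(w_ls)), 1e-8)
    }
  })
})

test_that("deconvolution is linear and weighting reduces to averaging", {
  withr::with_seed(9, {
    fs <- 1000; n <- 2000
    x <- as.numeric(stats::runif(n) < 0.05)
    y1 <- matrix(stats::rnorm(n), 1)
    y2 <- matrix(stats::rnorm(n), 1)
    wa <- deconvolve(x, y1, fs = fs)
    wb <- deconvolve(x, y2, fs = fs)
    wsum <- deconvolve(x, y1 + y2, fs = fs)
    expect_equal(wsum$w, wa$w + wb$w, tolerance = 1e-10)
    wscaled <- deconvolve(x, 3 * y1, fs = fs)
    expect_equal(wscaled$w, 3 * wa$w, tolerance = 1e-10)
    # equal-variance epochs: weighted result equals the plain mean
    y <- rbind(y1, y1[1, ] * -1 + 2 * y1[1, ])      # identical variances
    w_eq <- deconvolve(x, y, fs = fs)
    w_pl <- deconvolve(x, y, fs = fs, weights = c(0.5, 0.5))
    expect_equal(w_eq$w, w_pl$w, tolerance = 1e-12)
  })
})

test_that("half-wave rectified regressors recombine during averaging", {
  withr::with_seed(13, {
    fs <- 1000; n <- 4000
    audio <- stats::rnorm(n)
    parts <- halfwave_regressor(audio)
    expect_equal(parts$pos - parts$neg, audio)
    expect_true(all(parts$pos >= 0) && all(parts$neg >= 0))
    # EEG responding to the full audio: pos/neg pathway recovers the kernel
    h <- stats::dnorm(seq(-2, 2, length.out = 15))
    idx <- outer(seq_len(n), 0:14, function(i, k) ((i - k - 1) %% n) + 1)
    y <- as.numeric(matrix(audio[idx], n, 15) %*% h)
    w <- deconvolve(list(list(pos = parts$pos, neg = parts$neg)),
                    matrix(y, 1), fs = fs, lag_range = NULL)
    # each rectified stream sees the same system with the same polarity;
    # the averaged responses reproduce the kernel shape (the rectified
    # parts share structure, so the amplitude is biased, not the shape)
    expect_gt(stats::cor(w$w[w$lag >= 0][1:15], h), 0.99)
  })
})

test_that("filter presets are causal and follow Butterworth attenuation", {
  fs <- 10000
  n <- 2 * fs
  imp <- fake_response(c(numeric(n / 2), 1, numeric(n / 2 - 1)), fs)
  out <- filter_response(imp, "abr")
  expect_lt(max(abs(out$w[out$lag < 0])), 1e-12)    # causal
  expect_identical(out$provenance, c("bp30-2000hz_o1", "hp150hz_o1"))

  # DC offset removed by every preset
  dc <- fake_response(rep(1, n), fs)
  for (p in c("abr_mlr", "abr", "early_abr", "full_range")) {
    fo <- filter_response(dc, p)
    expect_lt(abs(fo$w[length(fo$w)]), 0.02)
  }

  # 100 Hz tone through the abr preset: gain = product of the analytic
  # first-order Butterworth responses (30 Hz HP, 2000 Hz LP, 150 Hz HP)
  t <- (0:(n - 1)) / fs
  tone <- fake_response(sin(2 * pi * 100 * t), fs)
  fo <- filter_response(tone, "abr")
  ss <- (n - fs):n
  g <- sqrt(mean(fo$w[ss]^2) / 0.5)
  g_want <- (100 / sqrt(100^2 + 30^2)) * (2000 / sqrt(100^2 + 2000^2)) *
    (100 / sqrt(100^2 + 150^2))
  expect_equal(20 * log10(g), 20 * log10(g_want), tolerance = 0.2)

  expect_warning(filter_response(out, "abr"), "already")
})

test_that("common component estimation and subtraction behave linearly", {
  withr::with_seed(21, {
    fs <- 10000; n <- 8000
    fakes <- lapply(1:6, function(i) as.numeric(stats::runif(n) < 0.06))
    noise <- matrix(stats::rnorm(4 * n), 4)
    rec <- epoched_recording(noise, fs)
    cc <- common_component(rec, fakes)
    # pure noise: the fake-train average shrinks toward zero
    single <- deconvolve(fakes[[1]], rec)
    expect_lt(stats::sd(cc$w), stats::sd(single$w))
    expect_error(common_component(rec, fakes[1]), "at least 2")
    expect_error(common_component(rec, fakes, true_regressors = fakes[2]),
                 "identical")

    # a shared onset-locked component is recovered and subtracted to zero
    h <- stats::dnorm(seq(-2, 2, length.out = 25))
    shared <- as.numeric(stats::runif(n) < 0.06)
    idx <- outer(seq_len(n), 0:24, function(i, k) ((i - k - 1) %% n) + 1)
    sig <- as.numeric(matrix(shared[idx], n, 25) %*% h)
    rec2 <- epoched_recording(matrix(rep(sig, 2), 2, byrow = TRUE), fs)
    band <- deconvolve(shared, rec2)
    cc2 <- common_component(rec2, list(shared, shared))
    out <- subtract_common(list(band), cc2)[[1]]
    expect_lt(max(abs(out$w)), 1e-10)
    expect_identical(utils::tail(out$provenance, 1), "common-subtracted")

    # zero common leaves responses untouched
    zero <- cc2; zero$w <- zero$w * 0
    expect_equal(subtract_common(list(band), zero)[[1]]$w, band$w)

    # mismatched provenance is rejected
    bandf <- filter_response(band, "abr_mlr")
    expect_error(subtract_common(list(bandf), cc2), "provenance")
  })
})

test_that("normalization factor is the ratio of mean response SDs", {
  mk <- function(sd_target) {
    w <- numeric(10000)
    idx <- 5001:5200                       # 0-20 ms at 10 kHz
    w[idx] <- rep(c(-1, 1), 100) * sd_target
    fake_response(w, 10000)
  }
  g1 <- normalization_factor(list(mk(1)), list(mk(1)))
  expect_equal(g1$g, 1)
  g2 <- normalization_factor(list(mk(2)), list(mk(4)))
  expect_equal(g2$g, 0.5, tolerance = 1e-3)
  g3 <- normalization_factor(list(mk(1), mk(3)), list(mk(2), mk(2)))
  expect_equal(g3$g, 1, tolerance = 1e-3)
  expect_error(normalization_factor(list(mk(1)), list(mk(0))), "zero SD")

  scaled <- apply_normalization(mk(2), g2)
  expect_equal(stats::sd(scaled$w[5001:5200]),
               2 * g2$g, tolerance = 1e-2)
  back <- apply_normalization(scaled, g2, direction = "divide")
  expect_equal(back$w, mk(2)$w, tolerance = 1e-12)
})
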