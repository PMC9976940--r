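test_that("downsampling preserves the passband and rejects aliases", {
  fs <- 20000; n <- 20000; t <- (0:(n - 1)) / fs

  # DC passes the anti-aliasing low-pass untouched
  dc <- ues_recording(matrix(rep(2.5, n)), fs, "A-P")
  d <- downsample(dc, 4000)
  expect_equal(d$fs, 4000)
  expect_equal(nrow(d$samples), 4000L)
  mid <- 500:3500
  expect_equal(d$samples[mid, 1], rep(2.5, length(mid)), tolerance = 1e-6)

  # a 50 Hz unit sinusoid survives with amplitude within 1 % (FFT peak)
  r50 <- ues_recording(matrix(sin(2 * pi * 50 * t)), fs, "A-P")
  y <- downsample(r50, 4000)$samples[mid, 1]
  spec <- Mod(fft(y * signal::hanning(length(y))))
  peak_bin <- which.max(spec[1:(length(y) / 2)])
  expect_equal((peak_bin - 1) * 4000 / length(y), 50, tolerance = 2)
  expect_equal(max(abs(y)), 1, tolerance = 0.01)

  # a 3 kHz tone (above the 2 kHz target Nyquist) is attenuated >= 40 dB
  r3k <- ues_recording(matrix(sin(2 * pi * 3000 * t)), fs, "A-P")
  y3 <- downsample(r3k, 4000)$samples[mid, 1]
  atten_db <- 20 * log10(sqrt(0.5) / rms_of(y3))
  expect_gte(atten_db, 40)

  # non-integer decimation ratios are unsupported
  expect_error(downsample(r50, 3000), "unsupported rate")
})

test_that("modified covariance AR fit recovers a planted model via BIC", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(100000), c(0.75, -0.5),
                                method = "recursive"))
  m <- fit_device_noise_model(x, max_order = 10)
  expect_equal(m$order, 2L)
  expect_equal(m$coefficients, c(0.75, -0.5), tolerance = 0.02)

  # determinism for fixed input
  m2 <- fit_device_noise_model(x, max_order = 10)
  expect_identical(m$coefficients, m2$coefficients)

  # search range contract: selected order never exceeds max_order, and the
  # selected model is stationary
  spec <- sim_spec(seed = 3)
  z <- generate_zero_input(spec, duration_ms = 1000, seed = 4)
  zd <- downsample(z, 4000)
  m20 <- fit_device_noise_model(zd$samples[, 1], max_order = 20)
  expect_lte(m20$order, 20L)
  r <- polyroot(c(-rev(m20$coefficients), 1))
  expect_true(all(Mod(r) < 1))

  # degenerate input
  expect_error(fit_device_noise_model(rep(1, 5000)), "degenerate")
})

test_that("whitening filter is the AR inverse and flattens model noise", {
  expect_equal(build_whitening_filter(ar_noise_model(c(0, 0, 0))),
               c(1, 0, 0, 0))
  expect_equal(build_whitening_filter(ar_noise_model(c(0.75, -0.5))),
               c(1, -0.75, 0.5))

  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(200000), c(0.75, -0.5),
                                method = "recursive"))
  taps <- build_whitening_filter(ar_noise_model(c(0.75, -0.5)))
  w <- as.numeric(stats::filter(x, taps, method = "convolution", sides = 1))
  w <- w[!is.na(w)]
  ac <- acf(w, lag.max = 10, plot = FALSE)$acf[-1]
  expect_lt(max(abs(ac)), 0.03)

  # whitening increases spectral flatness
  flatness <- function(v) {
    p <- Mod(fft(v))^2
    p <- p[2:(length(v) / 2)]
    exp(mean(log(p))) / mean(p)
  }
  expect_gt(flatness(w[1:2^17]), flatness(x[1:2^17]))
})

test_that("spline detrending removes drift and preserves the burst band", {
  expect_equal(spline_knot_count(40000, 3, 4000), 30L)

  fs <- 4000; n <- 40000; t <- (0:(n - 1)) / fs
  drift <- sin(2 * pi * 0.3 * t)
  resid <- remove_motion_artifacts(drift, fl = 3, fs = fs)
  expect_lt(sum(resid^2) / sum(drift^2), 0.05)

  tone <- sin(2 * pi * 70 * t)
  out <- remove_motion_artifacts(tone, fl = 3, fs = fs)
  expect_equal(max(abs(out[2000:38000])), 1, tolerance = 0.05)

  # linear in the input, and exact on its own spline space
  mix <- drift + tone
  out_mix <- remove_motion_artifacts(mix, fl = 3, fs = fs)
  expect_equal(out_mix, resid + out, tolerance = 1e-9)
  line <- 0.5 + 0.001 * seq_len(n)   # affine signals lie in the spline space
  expect_lt(max(abs(remove_motion_artifacts(line, fl = 3, fs = fs))), 1e-6)

  expect_error(remove_motion_artifacts(rnorm(100), fl = 3, fs = 4000),
               "too short")
})

test_that("the full chain cleans a synthetic swallow end to end", {
  spec <- sim_spec(n_swallows = 1, drift_amp = 0.5, ar_sd = 0.05,
                   noise_sd = 0.05, seed = 17)
  models <- local({
    z <- generate_zero_input(spec, duration_ms = 2000, seed = 99)
    fit_device_noise_models(downsample(z, 4000), max_order = 10)
  })
  sw <- generate_swallow(spec, 0.6, seed = 23)
  clean <- preprocess(sw$recording, noise_models = models)

  expect_equal(clean$fs, 4000)
  expect_length(clean$stages, 4L)
  expect_match(clean$stages[1], "^downsample")
  expect_match(clean$stages[2], "^whiten")
  expect_match(clean$stages[3], "^detrend")
  expect_match(clean$stages[4], "^wavelet")

  # correlation with the planted clean burst inside the UES window
  burst4k <- downsample(ues_recording(sw$components$burst, spec$fs_raw),
                        4000)$samples
  win <- ues_window_idx(sw, 4000)
  cc <- cor(clean$samples[win, 1], burst4k[win, 1])
  expect_gte(abs(cc), 0.8)

  # all-zero input maps to all-zero output through every stage
  z0 <- ues_recording(matrix(0, 20000, 3), 20000)
  c0 <- preprocess(z0, noise_models = models)
  expect_equal(max(abs(c0$samples)), 0)

  # channel-count mismatch with the noise models is a configuration error
  expect_error(preprocess(sw$recording, noise_models = models[1:2]),
               "configuration error")

  # recordings already at the working rate skip decimation, flagged
  rec4k <- ues_recording(matrix(rnorm(12000), ncol = 3), 4000)
  c4 <- preprocess(rec4k, noise_models = models)
  expect_match(c4$stages[1], "skipped")
  expect_length(c4$stages, 4L)
})

test_that("noise-model sidecars round-trip through text", {
  m <- ar_noise_model(c(0.6, -0.3, 0.1), bic = -1234.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_noise_model(m, path)
  m2 <- read_noise_model(path)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-10)
  expect_equal(m2$order, 3L)
})
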