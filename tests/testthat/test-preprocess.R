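test_that("polyphase down-sampling keeps duration and spectral content", {
  set.seed(1)
  rec <- make_sine_recording(c(10, 10), fs = 1000, duration = 30,
                             noise_sd = 0.01)
  out <- resample_recording(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$samples), 30 * 256)   # duration preserved
  # spectral oracle: the 10 Hz peak survives at the new rate
  ps <- welch_psd(epoch_recording(out, discard_s = 2, epoch_s = 4),
                  window_s = 1)
  peak <- ps$freqs[which.max(ps$power[1, ])]
  expect_lt(abs(peak - 10), 1 + 1e-9)
  # identity and error branches
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(out, 1000), "upsampling")
  expect_error(resample_recording(rec, 60), "80 Hz")
})

test_that("a 300 s 1 kHz recording resampled to 256 Hz has 76800 samples", {
  rec <- recording(matrix(rnorm(2 * 300 * 1000), 2), 1000, c("A", "B"))
  out <- resample_recording(rec, 256)
  expect_identical(ncol(out$samples), 76800L)
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  set.seed(2)
  rec <- make_sine_recording(c(3, 7, 11, 19), fs = 64, duration = 2,
                             noise_sd = 1)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$samples))), 1e-10)
  out2 <- rereference_average(out)
  expect_equal(out2$samples, out$samples, tolerance = 1e-12)
  # zero-mean input (x and -x) passes through unchanged
  x <- rnorm(100)
  rec2 <- recording(rbind(x, -x), 50, c("A", "B"))
  expect_equal(rereference_average(rec2)$samples, rec2$samples,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-phase band-pass attenuates per its analytic response", {
  fs <- 256
  t <- (0:(fs * 8 - 1)) / fs
  mk <- function(f) recording(rbind(sin(2 * pi * f * t),
                                    cos(2 * pi * f * t)), fs, c("A", "B"))
  # oracle: the designed filter's own frequency response, squared for the
  # forward-backward application
  h2_at <- function(f, lo, hi, order = 4) {
    flt <- signal::butter(order, c(lo, hi) / (fs / 2), "pass")
    z <- exp(-1i * 2 * pi * f / fs * (0:(length(flt$b) - 1)))
    Mod(sum(flt$b * z) / sum(flt$a * z))^2
  }
  trim <- (fs + 1):(fs * 7)   # drop filter edge transients

  out60 <- bandpass(mk(60), 0.5, 40)
  ratio60 <- sd(out60$samples[1, trim]) / sd(mk(60)$samples[1, trim])
  expect_lt(ratio60, 0.05)
  expect_equal(ratio60, h2_at(60, 0.5, 40), tolerance = 0.05)
  # the zero-phase FIR alternative reaches the 1 % residual mark at 60 Hz
  out60b <- bandpass(mk(60), 0.5, 40, type = "fir")
  expect_lt(sd(out60b$samples[1, trim]) / sd(mk(60)$samples[1, trim]), 0.01)
  # >= 40 dB one octave outside the band at the default order
  out80 <- bandpass(mk(80), 0.5, 40)
  expect_lt(sd(out80$samples[1, trim]) / sd(mk(80)$samples[1, trim]), 0.01)

  # pass-band: 10 Hz through the alpha band, amplitude within 5 %, zero phase
  out10 <- bandpass(mk(10), 8, 13)
  expect_equal(sd(out10$samples[1, trim]) / sd(mk(10)$samples[1, trim]), 1,
               tolerance = 0.05)
  xc <- ccf(out10$samples[1, trim], mk(10)$samples[1, trim],
            lag.max = 5, plot = FALSE)
  expect_identical(xc$lag[which.max(xc$acf)], 0)   # zero-phase

  # DC removal (trim generously: the 0.5 Hz edge settles slowly)
  recdc <- recording(matrix(5, 2, fs * 30), fs, c("A", "B"))
  outdc <- bandpass(recdc, 0.5, 40)
  trim_dc <- (8 * fs + 1):(22 * fs)
  expect_lt(abs(mean(outdc$samples[1, trim_dc])), 0.05)

  expect_error(bandpass(mk(10), 40, 0.5), "invalid band")
  expect_error(bandpass(mk(10), 0.5, 200), "invalid band")
})

test_that("re-referencing and linear filtering commute", {
  set.seed(3)
  rec <- make_sine_recording(c(5, 9, 14, 21), fs = 128, duration = 4,
                             noise_sd = 0.5)
  a <- bandpass(rereference_average(rec), 0.5, 40)
  b <- rereference_average(bandpass(rec, 0.5, 40))
  expect_lt(max(abs(a$samples - b$samples)), 1e-8)
})

test_that("epoching reproduces the study contract and its boundaries", {
  mk <- function(dur) recording(matrix(rnorm(2 * dur * 64), 2), 64,
                                c("A", "B"))
  ep <- epoch_recording(mk(300), discard_s = 60, epoch_s = 20)
  expect_identical(dim(ep$data)[1], 12L)
  expect_identical(dim(ep$data)[3], 20L * 64L)
  expect_identical(dim(epoch_recording(mk(100), 60, 20)$data)[1], 2L)
  expect_error(epoch_recording(mk(79), 60, 20), "0 epochs")
  expect_error(epoch_recording(mk(50), 60, 20), "discard")
  # epochs tile the retained samples without overlap
  rec <- mk(100)
  ep2 <- epoch_recording(rec, 60, 20)
  expect_equal(ep2$data[1, , ], rec$samples[, 60 * 64 + (1:(20 * 64))],
               ignore_attr = TRUE)
  expect_equal(ep2$data[2, , ], rec$samples[, 80 * 64 + (1:(20 * 64))],
               ignore_attr = TRUE)
})

test_that("epoched data round-trips through the TSV layout", {
  set.seed(6)
  rec <- make_sine_recording(c(9, 11), fs = 32, duration = 50,
                             noise_sd = 0.2)
  ep <- epoch_recording(rec, discard_s = 10, epoch_s = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_epochs_tsv(ep, path)
  back <- read_epochs_tsv(path)
  expect_equal(back$data, ep$data, tolerance = 1e-6)
  expect_identical(back$channel_labels, ep$channel_labels)
  expect_identical(back$fs, ep$fs)
  expect_identical(back$epoch_length_s, ep$epoch_length_s)
})

test_that("Welch PSD localises tones, is flat for white noise, and is additive", {
  fs <- 128
  set.seed(4)
  rec <- make_sine_recording(c(10, 10), fs = fs, duration = 100,
                             noise_sd = 0.01)
  ep <- epoch_recording(rec, 0, 20)
  ps <- welch_psd(ep)
  expect_identical(ps$freqs[which.max(ps$power[1, ])], 10)
  expect_equal(diff(ps$freqs)[1], 2)   # 500 ms window -> 2 Hz resolution

  # white noise: max/min bin ratio below 2 over 1-40 Hz with many segments
  wn <- recording(matrix(rnorm(2 * 60 * fs), 2), fs, c("A", "B"))
  psw <- welch_psd(epoch_recording(wn, 0, 20))
  sel <- psw$freqs >= 2 & psw$freqs <= 40
  expect_lt(max(psw$power[1, sel]) / min(psw$power[1, sel]), 2)

  # Parseval-style additivity of independent signals
  x <- rnorm(40 * fs); y <- as.numeric(scale(band_limited <- stats::filter(
    rnorm(40 * fs), rep(1 / 4, 4), sides = 1)))
  y[is.na(y)] <- 0
  mkrec <- function(v) recording(rbind(v, v), fs, c("A", "B"))
  tot <- function(v) sum(welch_psd(epoch_recording(mkrec(v), 0, 20))$power[1, ])
  expect_equal(tot(x + y), tot(x) + tot(y), tolerance = 0.05)

  expect_error(welch_psd(ep, window_s = 30), "longer than")
  expect_error(welch_psd(ep, window_s = 0.01), "window too short")
})

test_that("relative band power behaves as an integral ratio", {
  fs <- 128
  set.seed(5)
  rec <- make_sine_recording(c(10, 10), fs = fs, duration = 60,
                             noise_sd = 0.05)
  ps <- welch_psd(epoch_recording(rec, 0, 20))
  expect_equal(unname(relative_band_power(ps, c(0.5, 40), c(0.5, 40))),
               c(1, 1))
  frac <- relative_band_power(ps, c(8, 13), c(0.5, 40))
  expect_gt(frac[[1]], 0.95)
  expect_error(relative_band_power(ps, c(4, 8), c(8, 13)), "contained")
})
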