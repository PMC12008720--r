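test_that("cross-spectra: self-spectra are real, lags show as phase, 79 segments", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  tau <- 3   # samples
  x <- sin(2 * pi * 8 * t)
  y <- c(rep(0, tau), x)[1:length(x)]   # x delayed by tau samples
  rec <- recording(rbind(x, y), fs, c("A", "B"))
  ep <- epoch_recording(rec, 0, 20)
  cs <- cross_spectra(ep)
  expect_identical(cs$n_segments, 79L)   # floor((20-0.5)/0.25)+1

  X_aa <- cross_spectrum_pair(cs, 1, 1)
  expect_lt(max(abs(Im(X_aa))), 1e-6 * max(Mod(X_aa)))

  X_ab <- cross_spectrum_pair(cs, 1, 2)
  bin8 <- which(cs$freqs == 8)
  ph <- Arg(X_ab[, bin8])
  expect_equal(mean(ph), 2 * pi * 8 * tau / fs, tolerance = 1e-3)

  expect_error(cross_spectra(epoch_recording(rec, 0, 20), window_s = 19),
               "fewer than 2")
})

test_that("wPLI: saturates for a lagged pair, zeroes for identical signals", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- c(rep(0, 3), x)[1:length(x)]
  rec <- recording(rbind(x, y), fs, c("A", "B"))
  cs <- cross_spectra(epoch_recording(rec, 0, 20))
  W <- wpli_band(cs, c(10, 10))[[1]]$W     # carrier bin only
  expect_equal(W[1, 2], 1, tolerance = 1e-9)

  rec_same <- recording(rbind(x, x), fs, c("A", "B"))
  cs_same <- cross_spectra(epoch_recording(rec_same, 0, 20))
  W0 <- wpli_band(cs_same, c(8, 13))[[1]]$W
  expect_identical(W0[1, 2], 0)            # 0/0 convention

  expect_error(wpli_band(cs, c(100, 110)), "no frequency bins")
})

test_that("vectorised wPLI equals the per-definition oracle (3 ch x 4 segments)", {
  fs <- 64
  set.seed(21)
  # epoch of 1.25 s with 0.5 s windows, 50 % overlap -> exactly 4 segments
  rec <- make_sine_recording(c(9, 10, 11), fs = fs, duration = 62,
                             phases = c(0, 1, 2), noise_sd = 1)
  ep <- epoch_recording(rec, 60, 1.25)
  cs <- cross_spectra(ep)
  expect_identical(cs$n_segments, 4L)
  W_impl <- wpli_band(cs, c(8, 13))[[1]]$W
  W_orac <- oracle_wpli(ep$data[1, , ], fs, c(8, 13))
  expect_equal(W_impl, W_orac, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("wPLI is exactly invariant to positive channel rescaling", {
  fs <- 128
  set.seed(22)
  rec <- make_sine_recording(c(10, 10, 10), fs = fs, duration = 20,
                             phases = c(0, 0.7, 1.9), noise_sd = 0.5)
  cs1 <- cross_spectra(epoch_recording(rec, 0, 20))
  rec2 <- rec
  rec2$samples[2, ] <- 37.5 * rec2$samples[2, ]
  cs2 <- cross_spectra(epoch_recording(rec2, 0, 20))
  expect_equal(wpli_band(cs1, c(8, 13))[[1]]$W,
               wpli_band(cs2, c(8, 13))[[1]]$W, tolerance = 1e-12)
})

test_that("independent channels sit at the Monte-Carlo null level", {
  fs <- 128
  set.seed(23)
  vals <- replicate(60, {
    rec <- recording(matrix(rnorm(2 * 20 * fs), 2), fs, c("A", "B"))
    cs <- cross_spectra(epoch_recording(rec, 0, 20), fmax = 42)
    wpli_band(cs, c(8, 13))[[1]]$W[1, 2]
  })
  # K = 79 segments: null scale ~ 1/sqrt(pi*K/2) ~ 0.09
  expect_gt(mean(vals), 0.05)
  expect_lt(mean(vals), 0.25)
})

test_that("wPLI stays within [0,1] and matrices stay symmetric on noise", {
  fs <- 128
  set.seed(24)
  rec <- recording(matrix(rnorm(5 * 40 * fs), 5), fs, paste0("ch", 1:5))
  cs <- cross_spectra(epoch_recording(rec, 0, 20), fmax = 42)
  for (m in wpli_band(cs, c(8, 13))) {
    expect_true(all(m$W >= 0 & m$W <= 1))
    expect_identical(m$W, t(m$W))
    expect_true(all(diag(m$W) == 0))
  }
})

test_that("subject adjacency is the element-wise epoch mean", {
  labels <- c("A", "B", "C")
  mk <- function(v) taugraph:::new_connectivity_matrix(
    matrix(c(0, v, 0, v, 0, 0, 0, 0, 0), 3, 3), c(8, 13), labels)
  same <- subject_adjacency(replicate(12, mk(0.4), simplify = FALSE))
  expect_equal(same$W[1, 2], 0.4)
  expect_identical(same$n_epochs, 12L)
  alt <- subject_adjacency(lapply(rep(c(0, 1), 6), mk))
  expect_equal(alt$W[1, 2], 0.5)
  bad <- mk(0.3); bad$channel_labels <- c("A", "B", "D")
  expect_error(subject_adjacency(list(mk(0.1), bad)), "label mismatch")
})

test_that("epoch averaging shrinks null-edge variance about 12-fold", {
  fs <- 128
  set.seed(25)
  single <- numeric(40); averaged <- numeric(40)
  for (r in 1:40) {
    rec <- recording(matrix(rnorm(2 * 120 * fs), 2), fs, c("A", "B"))
    per_ep <- wpli_band(cross_spectra(epoch_recording(rec, 0, 20),
                                      fmax = 42), c(8, 13))
    single[r] <- per_ep[[1]]$W[1, 2]
    averaged[r] <- subject_adjacency(per_ep)$W[1, 2]
  }
  ratio <- var(single) / var(averaged)
  expect_gt(ratio, 4)    # ~6 epochs here; allow Monte-Carlo slack
})

test_that("adjacency TSV round-trips", {
  set.seed(26)
  labels <- c("Fz", "Cz", "Pz")
  cm <- taugraph:::new_connectivity_matrix(random_weight_matrix(3) / 2,
                                           c(8, 13), labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_tsv(cm, path)
  back <- read_adjacency_tsv(path)
  expect_equal(back$W, cm$W, tolerance = 1e-12)
  expect_identical(back$channel_labels, labels)
})
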