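#' Down-sample a recording (anti-aliased polyphase)
#'
#' Polyphase rational-rate resampling via [signal::resample()]; the acquisition
#' rate (e.g. 1 kHz) is reduced to the analysis rate (256 Hz by convention
#' here) before any other conditioning. Upsampling is refused: the operation
#' is a down-sampler by contract.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz; must satisfy
#'   `80 < target_fs <= rec$fs` (the analysis band extends to 40 Hz, so the
#'   Nyquist rate must exceed 80 Hz).
#' @return A [recording()] at `target_fs`; identity when `target_fs == fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) stop("upsampling requested: target_fs > fs")
  if (target_fs <= 80) stop("target_fs must exceed 80 Hz (2 x 40 Hz band edge)")
  if (target_fs == rec$fs) return(rec)
  if (abs(rec$fs - round(rec$fs)) > 1e-9 ||
      abs(target_fs - round(target_fs)) > 1e-9) {
    stop("integer sampling rates required for rational resampling")
  }
  p <- as.integer(round(target_fs)); q <- as.integer(round(rec$fs))
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  out <- t(apply(rec$samples, 1, function(x) signal::resample(x, p, q)))
  recording(out, fs = target_fs, channel_labels = rec$channel_labels,
            condition = rec$condition, subject_id = rec$subject_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Re-reference to the common average
#'
#' Subtracts, at every time point, the mean over all electrodes. The output
#' channel mean is exactly zero at each sample; the operation is idempotent.
#'
#' @param rec A [recording()] with at least 2 channels.
#' @return Average-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 2) stop("average reference needs >= 2 channels")
  out <- sweep(rec$samples, 2, colMeans(rec$samples))
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
            condition = rec$condition, subject_id = rec$subject_id)
}

# Causal IIR/FIR filtering of the columns of x with zero initial conditions
# (numerator by convolution, denominator by recursion, both C-level and
# multivariate in one call).
filt_cols <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xx <- rbind(matrix(0, nb - 1, ncol(x)), x)
  y <- stats::filter(xx, b, method = "convolution", sides = 1)
  y <- y[nb:(nrow(x) + nb - 1L), , drop = FALSE]
  if (length(a) > 1) y <- stats::filter(y, -a[-1], method = "recursive")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# Zero-phase (forward-backward) filtering of columns. Edge padding is an
# even reflection tapered to zero by a raised-cosine ramp: the outer pad
# edges then match the filter's zero initial state and the inner junctions
# stay continuous, so the slowly settling near-DC high-pass poles are not
# excited. The pad is generous (>= 384 samples where the data allow).
filtfilt_cols <- function(b, a, x) {
  n <- nrow(x)
  npad <- min(max(3L * (max(length(a), length(b)) - 1L), 384L), n - 1L)
  ramp <- 0.5 * (1 - cos(pi * seq_len(npad) / npad))
  pre <- x[(npad + 1L):2, , drop = FALSE] * ramp
  post <- x[(n - 1L):(n - npad), , drop = FALSE] * rev(ramp)
  y <- filt_cols(b, a, rbind(pre, x, post))
  y <- filt_cols(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(npad + 1L):(npad + n), , drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass of order `order` (per edge) applied
#' forward-backward ([signal::filtfilt()]), so the net phase response is zero
#' -- mandatory here because phase-based connectivity follows. The effective
#' magnitude response is the squared one-pass response. An FIR alternative
#' (windowed-sinc via [signal::fir1()], also zero-phase) is available.
#'
#' @param rec A [recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order (default 4) or FIR length-1 when
#'   `type = "fir"` (default 256 taps then).
#' @param type `"butter"` (default) or `"fir"`.
#' @return Filtered [recording()].
#' @export
bandpass <- function(rec, lo, hi, order = 4, type = c("butter", "fir")) {
  stopifnot(inherits(rec, "recording"))
  type <- match.arg(type)
  fs <- rec$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2")
  }
  wn <- c(lo, hi) / (fs / 2)
  if (type == "butter") {
    flt <- signal::butter(order, wn, type = "pass")
    b <- flt$b; a <- flt$a
  } else {
    ntaps <- if (order > 8) order else 256
    b <- signal::fir1(ntaps, wn, type = "pass")
    a <- 1
  }
  out <- t(filtfilt_cols(b, a, t(rec$samples)))
  recording(out, fs = fs, channel_labels = rec$channel_labels,
            condition = rec$condition, subject_id = rec$subject_id)
}

#' Cut a recording into fixed-length epochs
#'
#' Drops the initial accommodation period, then cuts consecutive
#' non-overlapping epochs; remainder samples after the last whole epoch are
#' discarded. With the study contract (300 s recording, 60 s discard, 20 s
#' epochs) this yields exactly 12 epochs / 240 s.
#'
#' @param rec A [recording()].
#' @param discard_s Seconds discarded from the start (default 60).
#' @param epoch_s Epoch length in seconds (default 20).
#' @return An `epoched_eeg` object: `data` (epochs x channels x time array),
#'   `fs`, `epoch_length_s`, `band`, `channel_labels`, `condition`,
#'   `subject_id`.
#' @export
epoch_recording <- function(rec, discard_s = 60, epoch_s = 20) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  dur <- recording_duration(rec)
  if (dur <= discard_s) stop("recording shorter than the discard period")
  n_epochs <- floor((dur - discard_s) / epoch_s)
  if (n_epochs < 1) {
    stop(sprintf(paste0("epoching yields 0 epochs: %.1f s remain after the ",
                        "%g s discard, epoch length is %g s"),
                 dur - discard_s, discard_s, epoch_s))
  }
  len <- as.integer(round(epoch_s * fs))
  start0 <- as.integer(round(discard_s * fs))
  data <- array(0, dim = c(n_epochs, nrow(rec$samples), len))
  for (e in seq_len(n_epochs)) {
    idx <- (start0 + (e - 1L) * len + 1L):(start0 + e * len)
    data[e, , ] <- rec$samples[, idx]
  }
  structure(
    list(data = data, fs = fs, epoch_length_s = epoch_s, band = "broadband",
         channel_labels = rec$channel_labels, condition = rec$condition,
         subject_id = rec$subject_id),
    class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %s [%s, %s]: %d epochs x %d channels x %g s @ %g Hz\n",
              x$subject_id, x$condition, x$band, d[1], d[2],
              x$epoch_length_s, x$fs))
  invisible(x)
}

# Hamming window (symmetric), local so the spectral estimators are
# self-contained and bit-reproducible.
hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Segment-wise windowed FFT over all epochs: the shared front end of
# welch_psd() and cross_spectra(). Returns S[epoch, segment, channel, bin]
# (complex), the frequency grid, and the PSD normalisation 1/(fs * sum(w^2)).
segment_fft <- function(ep, window_s = 0.5, overlap_frac = 0.5,
                        fmax = NULL) {
  stopifnot(inherits(ep, "epoched_eeg"))
  fs <- ep$fs
  nwin <- as.integer(round(window_s * fs))
  if (nwin < 8) stop("window too short: need window_s * fs >= 8 samples")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0,1)")
  nt <- dim(ep$data)[3]
  if (nwin > nt) stop("Welch window longer than one epoch")
  step <- max(1L, as.integer(round(nwin * (1 - overlap_frac))))
  starts <- seq(1L, nt - nwin + 1L, by = step)
  k <- length(starts)
  w <- hamming_window(nwin)
  freqs <- (0:(nwin %/% 2)) * fs / nwin
  keep <- seq_along(freqs)
  if (!is.null(fmax)) keep <- which(freqs <= fmax + 1e-9)
  n_ep <- dim(ep$data)[1]; n_ch <- dim(ep$data)[2]
  S <- array(complex(real = 0), dim = c(n_ep, k, n_ch, length(keep)))
  idx <- as.vector(outer(0:(nwin - 1L), starts, `+`))
  for (e in seq_len(n_ep)) {
    Xe <- matrix(ep$data[e, , ], n_ch, nt)
    # all segments of all channels as columns of one matrix -> one FFT call
    A <- matrix(0, nwin, k * n_ch)
    for (ch in seq_len(n_ch)) {
      A[, ((ch - 1L) * k + 1L):(ch * k)] <- Xe[ch, idx]
    }
    A <- sweep(A, 2, colMeans(A))                # per-segment detrend (mean)
    ft <- stats::mvfft(A * w)                    # window recycles down rows
    ftk <- ft[keep, , drop = FALSE]
    dim(ftk) <- c(length(keep), k, n_ch)
    S[e, , , ] <- aperm(ftk, c(2, 3, 1))
  }
  list(S = S, freqs = freqs[keep], n_segments = k,
       psd_scale = 1 / (fs * sum(w^2)), nwin = nwin, fs = fs)
}

#' Write / read epoched data as TSV plus YAML sidecar
#'
#' Layout: one row per sample, epoch-major (all samples of epoch 1, then
#' epoch 2, ...), one column per channel with verbatim labels, plus a
#' leading `epoch` index column; fs, band, epoch length and condition go to
#' `<path>.yaml`.
#'
#' @param ep An `epoched_eeg`.
#' @param path TSV file path.
#' @return `path` invisibly; the reader returns an `epoched_eeg`.
#' @export
write_epochs_tsv <- function(ep, path) {
  stopifnot(inherits(ep, "epoched_eeg"))
  d <- dim(ep$data)
  blocks <- lapply(seq_len(d[1]), function(e) t(matrix(ep$data[e, , ],
                                                       d[2], d[3])))
  mat <- do.call(rbind, blocks)
  colnames(mat) <- ep$channel_labels
  out <- data.frame(epoch = rep(seq_len(d[1]), each = d[3]), mat,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = ep$fs, epoch_length_s = ep$epoch_length_s,
                        band = ep$band, condition = ep$condition,
                        subject_id = ep$subject_id),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_epochs_tsv
#' @export
read_epochs_tsv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.delim(path, check.names = FALSE)
  epochs <- sort(unique(df$epoch))
  labels <- setdiff(names(df), "epoch")
  nt <- sum(df$epoch == epochs[1])
  data <- array(0, dim = c(length(epochs), length(labels), nt))
  for (e in seq_along(epochs)) {
    data[e, , ] <- t(as.matrix(df[df$epoch == epochs[e], labels]))
  }
  structure(list(data = data, fs = meta$fs,
                 epoch_length_s = meta$epoch_length_s, band = meta$band,
                 channel_labels = labels, condition = meta$condition,
                 subject_id = meta$subject_id),
            class = "epoched_eeg")
}

#' Welch power spectral density
#'
#' Hamming-tapered, overlapping segment periodograms averaged over segments
#' and epochs; one-sided PSD in microvolt^2/Hz. Frequency resolution is
#' `1/window_s` (2 Hz for the default 500 ms window).
#'
#' @param ep An `epoched_eeg` from [epoch_recording()].
#' @param window_s Welch window length in seconds (default 0.5).
#' @param overlap_frac Fractional overlap between segments (default 0.5).
#' @return A `power_spectrum`: `freqs` (Hz), `power` (channels x freqs,
#'   microvolt^2/Hz), `fs`, `channel_labels`.
#' @export
welch_psd <- function(ep, window_s = 0.5, overlap_frac = 0.5) {
  sf <- segment_fft(ep, window_s, overlap_frac)
  S <- sf$S
  n_ch <- dim(S)[3]; n_f <- dim(S)[4]
  pw <- matrix(0, n_ch, n_f)
  n_avg <- dim(S)[1] * dim(S)[2]
  for (e in seq_len(dim(S)[1])) {
    for (s in seq_len(dim(S)[2])) {
      pw <- pw + Mod(matrix(S[e, s, , ], n_ch, n_f))^2
    }
  }
  pw <- pw * sf$psd_scale / n_avg
  # one-sided: double all bins except DC and (if present) Nyquist
  dbl <- rep(2, n_f)
  dbl[1] <- 1
  if (abs(sf$freqs[n_f] - sf$fs / 2) < 1e-9) dbl[n_f] <- 1
  pw <- sweep(pw, 2, dbl, `*`)
  structure(list(freqs = sf$freqs, power = pw, fs = sf$fs,
                 channel_labels = ep$channel_labels,
                 condition = ep$condition, subject_id = ep$subject_id),
            class = "power_spectrum")
}

#' Relative band power per channel
#'
#' Integral of the PSD over `band` divided by the integral over `total`,
#' per channel, with the integral taken as the rectangle rule on the uniform
#' frequency grid (sum of bins times the bin width -- the standard EEG
#' band-power convention; a trapezoid would half-weight the band's edge
#' bins, which carry taper leakage from in-band activity). Used for the
#' spectral "slowing" analysis (theta/alpha shift).
#'
#' @param ps A `power_spectrum` from [welch_psd()].
#' @param band Two-element Hz interval, must lie within `total`.
#' @param total Two-element Hz interval of the reference (default broadband
#'   0.5-40 Hz).
#' @return Named numeric vector of fractions in \[0,1\], one per channel.
#' @export
relative_band_power <- function(ps, band, total = c(0.5, 40)) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (band[1] < total[1] - 1e-9 || band[2] > total[2] + 1e-9) {
    stop("band must be contained in total")
  }
  df_ <- if (length(ps$freqs) > 1) diff(ps$freqs)[1] else 1
  integ <- function(interval) {
    sel <- which(ps$freqs >= interval[1] - 1e-9 &
                 ps$freqs <= interval[2] + 1e-9)
    if (length(sel) == 0) stop("no frequency bins inside the interval")
    rowSums(ps$power[, sel, drop = FALSE]) * df_
  }
  out <- integ(band) / integ(total)
  names(out) <- ps$channel_labels
  out
}
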