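#' Construct a multichannel EEG recording
#'
#' A `recording` holds one subject/condition block of resting-state EEG:
#' a channels x time sample matrix in microvolt, the sampling rate, montage
#' labels and condition tag. All preprocessing operations consume and return
#' this container.
#'
#' @param samples Numeric matrix, channels x time, in microvolt.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Unique montage labels (10-5 system names), one per
#'   row of `samples`.
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @param subject_id Subject identifier string.
#' @return Object of class `recording`.
#' @export
recording <- function(samples, fs, channel_labels,
                      condition = c("eyes_closed", "eyes_open"),
                      subject_id = "S001") {
  condition <- match.arg(condition)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric channels x time matrix")
  }
  if (anyNA(samples)) stop("samples contain NA")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (nrow(samples) < 2) stop("a recording needs at least 2 channels")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop("one channel label per row of samples required")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_labels = channel_labels, condition = condition,
         subject_id = as.character(subject_id)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

# ---------------------------------------------------------------------------
# Plain-text interchange: TSV sample matrix + YAML sidecar header

#' Write / read a recording as TSV matrix plus YAML sidecar
#'
#' The sample matrix is written time x channels (channel labels as header
#' row); sampling rate, condition and subject id go to `<path>.yaml`. This is
#' the package's canonical text interchange format; channel labels are
#' preserved verbatim.
#'
#' @param rec A [recording()].
#' @param path Path of the TSV file (sidecar written to `paste0(path,".yaml")`).
#' @return `write_recording_tsv` returns `path` invisibly;
#'   `read_recording_tsv` returns a [recording()].
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  mat <- t(rec$samples)
  colnames(mat) <- rec$channel_labels
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  meta <- list(fs = rec$fs, condition = rec$condition,
               subject_id = rec$subject_id,
               n_channels = length(rec$channel_labels))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  mat <- as.matrix(utils::read.delim(path, check.names = FALSE))
  recording(t(mat), fs = meta$fs, channel_labels = colnames(mat),
            condition = meta$condition, subject_id = meta$subject_id)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit): minimal reader/writer for whole-second
# continuous recordings with a common sampling rate across channels.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Minimal EDF writer: 1-second data records, 16-bit integers, per-channel
#' physical scaling from the data range. The duration is truncated to whole
#' seconds (EDF records are fixed-length); `fs` must be an integer.
#' Quantization error is bounded by (physical range)/65535 per channel.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste("condition", rec$condition), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  fld(rec$channel_labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, format = "g", digits = 7), 8)
  fld(formatC(pmax_, format = "g", digits = 7), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  # re-read the header-encoded physical range so scaling round-trips exactly
  pmin_ <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_ <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - pmin_[ch]) / scale_[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any single-rate EDF)
#'
#' @param path EDF file path.
#' @param condition,subject_id Optional overrides for the recording metadata
#'   (EDF carries them as free text).
#' @return A [recording()].
#' @export
read_edf <- function(path, condition = NULL, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  pid <- rd(80); rid <- rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2,
                     signed = TRUE, endian = "little")
      out[ch, idx] <- pmin_[ch] + (dig - dmin[ch]) * scale_[ch]
    }
  }
  cond <- condition
  if (is.null(cond)) {
    cond <- if (grepl("eyes_open", rid)) "eyes_open" else "eyes_closed"
  }
  recording(out, fs = fs, channel_labels = labels, condition = cond,
            subject_id = if (is.null(subject_id)) pid else subject_id)
}

# ---------------------------------------------------------------------------
# BrainVision reader (.vhdr INI header + multiplexed binary data file)

#' Read a BrainVision recording (.vhdr + binary data file)
#'
#' Supports the common export layout: `DataFormat=BINARY`,
#' `DataOrientation=MULTIPLEXED`, `BinaryFormat` of `IEEE_FLOAT_32` or
#' `INT_16` (with per-channel resolution). Channel labels are taken verbatim
#' from the `[Channel Infos]` section.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @param condition,subject_id Recording metadata (not stored by the format).
#' @return A [recording()].
#' @export
read_brainvision <- function(vhdr_path, condition = "eyes_closed",
                             subject_id = "S001") {
  lines <- readLines(vhdr_path, warn = FALSE)
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop("missing key in .vhdr: ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  if (toupper(get_kv("DataFormat")) != "BINARY") {
    stop("only BINARY BrainVision data supported")
  }
  if (toupper(get_kv("DataOrientation")) != "MULTIPLEXED") {
    stop("only MULTIPLEXED orientation supported")
  }
  binfmt <- toupper(get_kv("BinaryFormat"))
  n_ch <- as.integer(get_kv("NumberOfChannels"))
  si_us <- as.numeric(get_kv("SamplingInterval"))
  fs <- 1e6 / si_us
  data_file <- get_kv("DataFile")

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) < n_ch) stop("channel info incomplete in .vhdr")
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines[seq_len(n_ch)]), ",")
  labels <- vapply(parts, `[`, "", 1)
  resol <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0)

  data_path <- file.path(dirname(vhdr_path), data_file)
  sz <- file.info(data_path)$size
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (binfmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4
    raw_vals <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
  } else if (binfmt == "INT_16") {
    n_val <- sz / 2
    raw_vals <- readBin(con, "integer", n = n_val, size = 2, signed = TRUE,
                        endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", binfmt)
  }
  n_t <- floor(length(raw_vals) / n_ch)
  mat <- matrix(raw_vals[seq_len(n_t * n_ch)], nrow = n_ch)  # multiplexed
  mat <- mat * resol
  recording(mat, fs = fs, channel_labels = labels, condition = condition,
            subject_id = subject_id)
}
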