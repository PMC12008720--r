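#' Welch cross-spectra of an epoched recording
#'
#' Hamming-tapered, overlapping segments per epoch; per-segment FFT. The
#' cross-spectrum of a channel pair is \eqn{X_{ij}(f) = S_i(f)\,\overline{S_j(f)}};
#' it is held in factored form (the per-segment channel spectra `S`) and
#' materialised per pair on demand via [cross_spectrum_pair()], which is exact
#' and avoids a channels^2 x bins x segments x epochs array. With 20 s epochs,
#' 500 ms windows and 50 % overlap there are 79 segments per epoch.
#'
#' @param ep An `epoched_eeg` from [epoch_recording()].
#' @param window_s,overlap_frac Welch parameters (defaults 0.5 s / 0.5).
#' @param fmax Optional highest frequency (Hz) to retain (memory control).
#' @return A `cross_spectra` object: `S` (epochs x segments x channels x bins,
#'   complex), `freqs`, `n_segments`, `channel_labels`, `condition`.
#' @export
cross_spectra <- function(ep, window_s = 0.5, overlap_frac = 0.5,
                          fmax = NULL) {
  sf <- segment_fft(ep, window_s, overlap_frac, fmax = fmax)
  if (sf$n_segments < 2) {
    stop("fewer than 2 Welch segments: wPLI expectation undefined")
  }
  structure(list(S = sf$S, freqs = sf$freqs, n_segments = sf$n_segments,
                 channel_labels = ep$channel_labels,
                 condition = ep$condition, subject_id = ep$subject_id),
            class = "cross_spectra")
}

#' Materialise the cross-spectrum of one channel pair
#'
#' @param cs A `cross_spectra` object.
#' @param i,j Channel indices (or labels).
#' @param epoch Epoch index.
#' @return Complex matrix, segments x frequency bins:
#'   \eqn{X_{ij,k}(f) = S_{i,k}(f) \overline{S_{j,k}(f)}}.
#' @export
cross_spectrum_pair <- function(cs, i, j, epoch = 1) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (is.character(i)) i <- match(i, cs$channel_labels)
  if (is.character(j)) j <- match(j, cs$channel_labels)
  k <- dim(cs$S)[2]; nf <- dim(cs$S)[4]
  Si <- matrix(cs$S[epoch, , i, ], k, nf)
  Sj <- matrix(cs$S[epoch, , j, ], k, nf)
  Si * Conj(Sj)
}

new_connectivity_matrix <- function(W, band, channel_labels,
                                    condition = "eyes_closed",
                                    n_epochs = 1L, subject_id = "S001") {
  W <- as.matrix(W)
  dimnames(W) <- list(channel_labels, channel_labels)
  if (max(abs(W - t(W))) > 1e-10) stop("connectivity matrix not symmetric")
  diag(W) <- 0
  if (any(W < -1e-12) || any(W > 1 + 1e-12)) {
    stop("wPLI weights must lie in [0, 1]")
  }
  W <- pmin(pmax(W, 0), 1)
  structure(list(W = W, band = band, channel_labels = channel_labels,
                 condition = condition, n_epochs = as.integer(n_epochs),
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s [%s, %s]: %d channels, %d epoch(s), mean wPLI %.3f\n",
              x$subject_id, x$condition,
              paste(x$band, collapse = "-"), nrow(x$W), x$n_epochs,
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' Per-epoch weighted Phase Lag Index adjacency in a frequency band
#'
#' For each unordered channel pair and frequency bin,
#' \deqn{wPLI_{ij}(f) = \frac{|\sum_k \mathrm{Im}\,X_{ij,k}(f)|}{\sum_k |\mathrm{Im}\,X_{ij,k}(f)|}}
#' with \eqn{k} running over the Welch segments of the epoch, and 0 when the
#' denominator vanishes (identical/zero-lag signals are "not lag-coupled").
#' The band value is the unweighted mean over bins whose centres lie in
#' `[band[1], band[2]]` inclusive (at 2 Hz resolution the alpha band 8-13 Hz
#' selects bins 8, 10, 12). Entries are already nonnegative, matching the
#' absolute-value adjacency convention. A debiased squared estimator is
#' available behind `debias = TRUE` for sensitivity analyses.
#'
#' @param cs A `cross_spectra` object.
#' @param band Two-element Hz interval, e.g. `c(8, 13)` (alpha) or
#'   `c(4, 8)` (theta).
#' @param debias If `TRUE`, the debiased wPLI-square estimator is used
#'   instead of the plain estimator (default `FALSE`).
#' @return List of `connectivity_matrix`, one per epoch.
#' @export
wpli_band <- function(cs, band, debias = FALSE) {
  stopifnot(inherits(cs, "cross_spectra"))
  bins <- which(cs$freqs >= band[1] - 1e-9 & cs$freqs <= band[2] + 1e-9)
  if (length(bins) == 0) stop("band contains no frequency bins")
  n_ep <- dim(cs$S)[1]; k <- dim(cs$S)[2]; n_ch <- dim(cs$S)[3]
  out <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    acc <- matrix(0, n_ch, n_ch)
    for (b in bins) {
      Sb <- matrix(cs$S[e, , , b], k, n_ch)   # segments x channels
      Re_ <- Re(Sb); Im_ <- Im(Sb)
      num <- matrix(0, n_ch, n_ch); den <- matrix(0, n_ch, n_ch)
      if (debias) num2 <- matrix(0, n_ch, n_ch)
      for (s in seq_len(k)) {
        # Im(S_i conj(S_j)) = Im_i Re_j - Re_i Im_j
        imx <- tcrossprod(Im_[s, ], Re_[s, ]) - tcrossprod(Re_[s, ], Im_[s, ])
        num <- num + imx
        den <- den + abs(imx)
        if (debias) num2 <- num2 + imx^2
      }
      if (debias) {
        w <- (num^2 - num2) / pmax(den^2 - num2, .Machine$double.eps)
        w[den^2 - num2 <= 0] <- 0
        w <- pmin(pmax(w, 0), 1)
      } else {
        w <- abs(num) / den
        w[den == 0] <- 0
      }
      acc <- acc + w
    }
    W <- acc / length(bins)
    out[[e]] <- new_connectivity_matrix(W, band, cs$channel_labels,
                                        cs$condition, 1L, cs$subject_id)
  }
  out
}

#' Subject-level adjacency: average the per-epoch wPLI matrices
#'
#' Element-wise arithmetic mean over epochs (the study averages the wPLI over
#' the 12 epochs of a condition); symmetry and the \[0,1\] range are preserved.
#'
#' @param per_epoch List of `connectivity_matrix` with identical labels.
#' @return A single `connectivity_matrix` with `n_epochs` set to the count.
#' @export
subject_adjacency <- function(per_epoch) {
  if (length(per_epoch) < 1) stop("need at least one epoch matrix")
  labels <- per_epoch[[1]]$channel_labels
  for (m in per_epoch) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (!identical(m$channel_labels, labels)) {
      stop("channel label mismatch across epoch matrices")
    }
  }
  W <- Reduce(`+`, lapply(per_epoch, `[[`, "W")) / length(per_epoch)
  new_connectivity_matrix(W, per_epoch[[1]]$band, labels,
                          per_epoch[[1]]$condition, length(per_epoch),
                          per_epoch[[1]]$subject_id)
}

#' Write / read a connectivity matrix as labelled TSV
#'
#' @param cm A `connectivity_matrix`.
#' @param path TSV path (labels as header row and first column).
#' @return `path` invisibly; reader returns a `connectivity_matrix`.
#' @export
write_adjacency_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(label = cm$channel_labels, cm$W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @param band,condition Metadata to attach on read.
#' @export
read_adjacency_tsv <- function(path, band = c(8, 13),
                               condition = "eyes_closed") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- df[[1]]
  W <- as.matrix(df[, -1, drop = FALSE])
  new_connectivity_matrix(W, band, labels, condition)
}
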