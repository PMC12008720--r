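# Independent oracles and small fixture factories used across the suite.
# Oracles deliberately re-derive quantities from first principles (loops,
# enumeration, textbook formulas) and never call the implementation paths
# they check.

# -- fixtures ---------------------------------------------------------------

make_sine_recording <- function(freqs, fs = 128, duration = 10, amp = 1,
                                phases = NULL, noise_sd = 0,
                                n_channels = length(freqs)) {
  n <- duration * fs
  t <- (0:(n - 1)) / fs
  if (is.null(phases)) phases <- rep(0, n_channels)
  X <- t(sapply(seq_len(n_channels), function(ch) {
    amp * sin(2 * pi * freqs[ch] * t + phases[ch]) +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  }))
  recording(X, fs = fs, channel_labels = paste0("ch", seq_len(n_channels)))
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_group = c(cu_neg = 3L, cu_pos = 2L, prodromal = 2L),
                   duration_s = 100, fs = 128, n_channels = 8, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

random_weight_matrix <- function(n, density = 1) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- runif(sum(ut))
  if (density < 1) vals[runif(length(vals)) > density] <- 0
  W[ut] <- vals
  W + t(W)
}

# -- graph oracles ----------------------------------------------------------

# Onnela clustering by explicit triple enumeration.
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W)
  k <- rowSums(W > 0)
  ci <- numeric(n)
  for (i in 1:n) {
    if (k[i] < 2) next
    acc <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h) {
        acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    }
    ci[i] <- acc / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

# Characteristic path length via Floyd-Warshall on 1/w lengths.
oracle_path_length <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# -- wPLI oracle ------------------------------------------------------------

# Direct per-definition wPLI from raw epoch samples: hand-rolled Hamming
# window, per-segment FFT, Im of the cross-spectrum, band mean over bins.
oracle_wpli <- function(ep_data, fs, band, window_s = 0.5,
                        overlap_frac = 0.5) {
  n_ch <- dim(ep_data)[1]
  nt <- dim(ep_data)[2]
  nwin <- round(window_s * fs)
  step <- round(nwin * (1 - overlap_frac))
  starts <- seq(1, nt - nwin + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  freqs <- (0:(nwin %/% 2)) * fs / nwin
  bins <- which(freqs >= band[1] & freqs <= band[2])
  S <- array(0i, dim = c(length(starts), n_ch, nwin))
  for (s in seq_along(starts)) {
    for (ch in 1:n_ch) {
      seg <- ep_data[ch, starts[s]:(starts[s] + nwin - 1)]
      seg <- seg - mean(seg)
      S[s, ch, ] <- fft(seg * w)
    }
  }
  W <- matrix(0, n_ch, n_ch)
  for (i in 1:n_ch) for (j in 1:n_ch) {
    if (i == j) next
    vals <- numeric(length(bins))
    for (b in seq_along(bins)) {
      imx <- sapply(seq_along(starts), function(s) {
        Im(S[s, i, bins[b]] * Conj(S[s, j, bins[b]]))
      })
      den <- sum(abs(imx))
      vals[b] <- if (den == 0) 0 else abs(sum(imx)) / den
    }
    W[i, j] <- mean(vals)
  }
  W
}

# -- factor-analysis oracles ------------------------------------------------

tucker_congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best match of estimated factor columns to true columns over permutation
# and sign; returns the per-true-factor congruence.
best_congruence <- function(L_est, L_true) {
  m <- ncol(L_true)
  perms <- if (m == 2) list(1:2, 2:1) else list(seq_len(m))
  best <- rep(-Inf, m)
  for (p in perms) {
    cg <- sapply(seq_len(m), function(i) {
      abs(tucker_congruence(L_est[, p[i]], L_true[, i]))
    })
    if (mean(cg) > mean(best)) best <- cg
  }
  best
}

# -- misc -------------------------------------------------------------------

# Rank-residualize-then-correlate partial Spearman, the brute-force way.
oracle_partial_spearman <- function(x, y, Z) {
  rx <- resid(lm(rank(x) ~ as.matrix(apply(Z, 2, rank))))
  ry <- resid(lm(rank(y) ~ as.matrix(apply(Z, 2, rank))))
  cor(rx, ry)
}
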