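#' Configuration of the synthetic three-group cohort
#'
#' Encodes the study design the analysis assumes: three groups (amyloid
#' negative / amyloid positive cognitively unimpaired, and prodromal AD), a
#' latent per-subject disease severity s in \[0,1\] that drives (i) the decay
#' of lagged alpha-band inter-channel coupling, (ii) the theta/alpha
#' "slowing" shift, (iii) regional tau DVR (earliest and steepest in
#' perirhinal cortex) and (iv) episodic-memory factor scores. Group severity
#' ranges overlap deliberately, as biomarker stages do.
#'
#' @param n_per_group Named counts for `cu_neg`, `cu_pos`, `prodromal`
#'   (default 37/14/15, the study's included subset).
#' @param duration_s Seconds per condition (default 300; must be >= 80 so
#'   that at least one 20 s epoch survives the 60 s discard).
#' @param fs Sampling rate in Hz (default 256, the analysis rate).
#' @param n_channels Electrode count (default 128; labels from the shipped
#'   montage, or generic labels for non-standard counts).
#' @param severity_ranges Per-group severity intervals within \[0,1\].
#' @param coupling_base Baseline alpha-source coupling gain.
#' @param coupling_slope Relative change of coupling per unit severity
#'   (negative; default -0.5, i.e. coupling halves from s=0 to s=1).
#' @param phase_jitter_base Baseline per-channel slow phase-jitter SD in
#'   radians (default 0.2).
#' @param phase_jitter_slope Increase of the phase-jitter SD per unit
#'   severity (default 2.0 rad): severity degrades phase locking
#'   (hyposynchrony), the component of coupling that wPLI measures.
#' @param subject_jitter_sd SD of the half-normal per-subject baseline
#'   phase-jitter term (severity-independent between-subject spread in
#'   network synchrony; default 0.8 rad).
#' @param alpha_amp Alpha source amplitude (microvolt; halved for eyes-open).
#' @param theta_amp Baseline theta amplitude (microvolt).
#' @param theta_slope Relative increase of theta amplitude per unit severity.
#' @param noise_sd 1/f (pink) channel-noise standard deviation (microvolt).
#' @param zero_lag_gain Gain of a shared instantaneous (volume-conduction
#'   like) confound component; 0 (default) disables it. Used to verify that
#'   wPLI does not inflate under zero-lag mixing.
#' @param tau_base,tau_slopes,tau_noise_sd Named per-region DVR intercepts,
#'   severity slopes and noise SDs; the perirhinal slope must be the largest.
#' @param factor_loadings 10 x 2 neuropsych loading matrix (unit-bounded).
#' @param neuropsych_noise_sd Residual SD of the generated test scores.
#' @param confound_covariates If `TRUE`, age is drawn correlated with
#'   severity (optional confounding switch); default `FALSE` (covariates
#'   independent of severity, isolating the tau effect).
#' @param conditions Conditions to simulate (default eyes-closed only).
#' @param seed Integer master seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_per_group = c(cu_neg = 37L, cu_pos = 14L, prodromal = 15L),
    duration_s = 300, fs = 256, n_channels = 128,
    severity_ranges = list(cu_neg = c(0, 0.15), cu_pos = c(0.05, 0.45),
                           prodromal = c(0.45, 0.95)),
    coupling_base = 1.0, coupling_slope = -0.5,
    phase_jitter_base = 0.2, phase_jitter_slope = 2.0,
    subject_jitter_sd = 0.8,
    alpha_amp = 1.0, theta_amp = 0.35, theta_slope = 1.0,
    noise_sd = 1.0, zero_lag_gain = 0,
    tau_base = c(entorhinal = 0.73, perirhinal = 0.89,
                 hippocampus_caudal = 0.80, hippocampus_rostral = 0.82,
                 parahippocampus_lateral = 0.84, parahippocampus_medial = 0.82,
                 fusiform = 0.92, temporal_inferior = 0.95,
                 temporal_lateral = 0.93, parietal_inferior = 0.90,
                 parietal_medial = 0.88),
    tau_slopes = c(entorhinal = 0.43, perirhinal = 0.87,
                   hippocampus_caudal = 0.50, hippocampus_rostral = 0.50,
                   parahippocampus_lateral = 0.55, parahippocampus_medial = 0.55,
                   fusiform = 0.60, temporal_inferior = 0.45,
                   temporal_lateral = 0.40, parietal_inferior = 0.35,
                   parietal_medial = 0.35),
    tau_noise_sd = 0.07,
    factor_loadings = default_factor_loadings(),
    neuropsych_noise_sd = 0.55,
    confound_covariates = FALSE,
    conditions = "eyes_closed",
    seed = 1L) {
  cfg <- list(n_per_group = n_per_group, duration_s = duration_s, fs = fs,
              n_channels = as.integer(n_channels),
              severity_ranges = severity_ranges,
              coupling_base = coupling_base, coupling_slope = coupling_slope,
              phase_jitter_base = phase_jitter_base,
              phase_jitter_slope = phase_jitter_slope,
              subject_jitter_sd = subject_jitter_sd,
              alpha_amp = alpha_amp, theta_amp = theta_amp,
              theta_slope = theta_slope, noise_sd = noise_sd,
              zero_lag_gain = zero_lag_gain,
              tau_base = tau_base, tau_slopes = tau_slopes,
              tau_noise_sd = tau_noise_sd,
              factor_loadings = factor_loadings,
              neuropsych_noise_sd = neuropsych_noise_sd,
              confound_covariates = confound_covariates,
              conditions = conditions, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!all(c("cu_neg", "cu_pos", "prodromal") %in% names(cfg$n_per_group))) {
    stop("n_per_group needs cu_neg, cu_pos, prodromal")
  }
  if (any(cfg$n_per_group < 1)) stop("every group needs n >= 1")
  if (cfg$duration_s < 80) {
    stop("duration_s must be >= 80 (60 s discard + one 20 s epoch)")
  }
  if (cfg$fs < 128) stop("fs must be >= 128 Hz")
  if (cfg$n_channels < 2) stop("need at least 2 channels")
  for (rg in cfg$severity_ranges) {
    if (rg[1] < 0 || rg[2] > 1 || rg[1] > rg[2]) {
      stop("severity ranges must be ordered intervals within [0,1]")
    }
  }
  if (any(cfg$tau_base <= 0)) stop("tau base DVR values must be positive")
  slopes <- cfg$tau_slopes
  if (slopes["perirhinal"] < max(slopes)) {
    stop("the perirhinal tau slope must be >= every other slope")
  }
  if (!all(dim(cfg$factor_loadings) == c(10, 2))) {
    stop("factor_loadings must be 10 x 2")
  }
  if (any(abs(cfg$factor_loadings) > 1)) {
    stop("factor loadings must be unit-bounded")
  }
  invisible(cfg)
}

#' Default neuropsych factor loadings (10 tests x 2 factors)
#'
#' Factor 1 is episodic memory (verbal learning and recall tests), factor 2
#' language/semantic processing; the Trail-Making ratio loads negatively
#' (higher ratio = worse executive performance).
#'
#' @return 10 x 2 matrix, rows named by test.
#' @export
default_factor_loadings <- function() {
  tests <- c("AVLT_TL", "AVLT_DR", "BSRT_TR", "BSRT_DR", "BNT", "AVF",
             "LVF", "PALPA49", "TMT_BA", "RPM")
  L <- matrix(0, 10, 2, dimnames = list(tests, c("memory", "language")))
  L[, 1] <- c(0.85, 0.75, 0.88, 0.80, 0.15, 0.20, 0.10, 0.10, -0.10, 0.15)
  L[, 2] <- c(0.10, 0.15, 0.10, 0.10, 0.68, 0.65, 0.60, 0.55, -0.35, 0.45)
  L
}

channel_labels_for <- function(n_channels) {
  if (n_channels %in% c(128L, 64L, 32L, 24L)) return(montage_labels(n_channels))
  if (n_channels < 128L) return(montage_labels(128L)[seq_len(n_channels)])
  sprintf("E%03d", seq_len(n_channels))
}

# 1/f ("pink") noise by spectral shaping of white noise: amplitude ~ f^(-1/2)
# above 1 Hz, flat below, unit variance on output.
pink_noise <- function(n, fs) {
  wn <- stats::rnorm(n)
  ft <- stats::fft(wn)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]     # two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0                           # remove DC
  x <- Re(stats::fft(ft * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Raised-cosine band window on a frequency axis.
band_shape <- function(f, lo, hi, edge) {
  shape <- numeric(length(f))
  shape[f >= lo & f <= hi] <- 1
  rise <- f >= lo - edge & f < lo
  shape[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / edge))
  fall <- f > hi & f <= hi + edge
  shape[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / edge))
  shape
}

# Band-limited stochastic oscillation: white noise confined to [lo, hi] in
# the frequency domain with raised-cosine edges, unit variance.
band_noise <- function(n, fs, lo, hi, edge = 0.5) {
  wn <- stats::rnorm(n)
  ft <- stats::fft(wn)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  x <- Re(stats::fft(ft * band_shape(f, lo, hi, edge), inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# n_ch independent spectrally shaped noise channels in one batch FFT;
# shape_fun maps the folded (two-sided magnitude) frequency axis to an
# amplitude shape. Columns are scaled to unit variance.
noise_matrix <- function(n, n_ch, fs, shape_fun) {
  W <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  ft <- stats::mvfft(W)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  fm <- ifelse(f > fs / 2, fs - f, f)
  shape <- shape_fun(fm)
  x <- Re(stats::mvfft(ft * shape, inverse = TRUE)) / n
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, pmax(sds, 1e-300), `/`)
}

# Complex analytic band-limited noise (positive frequencies only), with the
# real part scaled to unit variance. Re(z e^{i phi}) phase-shifts the
# oscillation without touching its envelope.
analytic_band_noise <- function(n, fs, lo, hi, edge = 0.75) {
  wn <- stats::rnorm(n)
  ft <- stats::fft(wn)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  shape <- band_shape(f, lo, hi, edge)
  shape[f > fs / 2] <- 0                  # one-sided -> analytic signal
  z <- stats::fft(ft * shape, inverse = TRUE) / n
  s <- stats::sd(Re(z))
  if (s == 0) return(z)
  z / s
}

#' Simulate one subject's resting-state EEG
#'
#' All channels share a common alpha source (carrier drawn in 9-11 Hz with a
#' slow random-walk phase drift), mixed into each channel with a
#' channel-specific nonzero lag of 1-4 samples and coupling gain
#' `coupling_base * (1 + coupling_slope * severity)`; wPLI is blind to
#' zero-lag mixing, so genuine coupling is imposed with nonzero lags only.
#' Each channel adds independent 1/f noise and an independent band-limited
#' theta (4-8 Hz) oscillation whose amplitude grows with severity (the
#' "slowing" shift). Eyes-open halves the alpha source amplitude. With
#' `zero_lag_gain > 0` a shared instantaneous broadband component is mixed in
#' with channel-specific gains (volume-conduction confound switch). The
#' output is deterministic given `(config, severity, seed, condition)`.
#'
#' @param config A [cohort_config()].
#' @param severity Latent severity in \[0, 1\].
#' @param seed Integer seed for this recording.
#' @param condition `"eyes_closed"` (default) or `"eyes_open"`.
#' @param subject_id Subject identifier.
#' @return A [recording()] with attribute `"ground_truth"` (list: carrier
#'   frequency, per-channel lags in samples, per-channel coupling gains).
#' @export
simulate_subject_eeg <- function(config, severity, seed,
                                 condition = "eyes_closed",
                                 subject_id = "S001") {
  stopifnot(inherits(config, "cohort_config"))
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (config$duration_s < 80) {
    stop("duration too short for the epoching contract (60 s discard + 20 s epoch)")
  }
  set.seed(as.integer(seed))
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  n_ch <- config$n_channels
  max_lag <- 4L
  n_pad <- n + max_lag

  # Common alpha source: a band-limited stochastic oscillation centred on a
  # carrier drawn in 9-11 Hz (its intrinsic phase drifts slowly by
  # construction); held as an analytic signal so per-channel lags and phase
  # jitter act on the phase without touching the envelope.
  f0 <- stats::runif(1, 9, 11)
  half_bw <- 1.75
  z_src <- analytic_band_noise(n_pad, fs, f0 - half_bw, f0 + half_bw)
  t_ <- (0:(n_pad - 1)) / fs
  amp <- config$alpha_amp * if (condition == "eyes_open") 0.5 else 1

  # Channel lags are continuous within 1-4 samples so that every channel
  # pair has a nonzero relative lag (wPLI is blind to zero-lag coupling;
  # coinciding integer lags would silently zero out a quarter of the pairs).
  lags <- stats::runif(n_ch, 1, max_lag)
  # Channel-specific source-projection phase (propagation/dipole geometry):
  # spreads pairwise phase offsets around the circle so that lagged coupling
  # is wPLI-visible for essentially every pair, not only for pairs whose
  # 1-4-sample lags happen to differ.
  theta_ch <- stats::runif(n_ch, 0, 2 * pi)
  # Heterogeneous degradation: each channel's severity effect is scaled by a
  # channel-specific random factor, so high severity both weakens and
  # de-homogenises the genuine edges (a uniform attenuation alone would
  # leave the max-normalised clustering coefficient unchanged).
  atten <- stats::runif(n_ch, 0.4, 1.6)
  g <- config$coupling_base * (1 + config$coupling_slope * severity * atten) *
    stats::runif(n_ch, 0.9, 1.1)
  g <- pmax(g, 0)
  # Phase decoherence (alpha hyposynchrony): wPLI is amplitude-blind, so the
  # severity effect on phase coupling is carried by per-channel slow phase
  # jitter whose standard deviation (radians) grows with severity. A
  # half-normal per-subject baseline term adds the severity-independent
  # between-subject spread in network synchrony seen in healthy cohorts.
  subj_jit <- abs(stats::rnorm(1, 0, config$subject_jitter_sd))
  jitter_sd <- config$phase_jitter_base + subj_jit +
    config$phase_jitter_slope * severity * atten
  theta_amp <- config$theta_amp * (1 + config$theta_slope * severity)

  shared_zero_lag <- if (config$zero_lag_gain > 0) {
    config$zero_lag_gain * pink_noise(n, fs)
  } else NULL
  zl_gain <- if (!is.null(shared_zero_lag)) stats::runif(n_ch, 0.5, 1.5)

  # batch-generated independent noise components (one FFT per component)
  jit_mat <- noise_matrix(n, n_ch, fs,
                          function(f) band_shape(f, 0.05, 3, 0.5))
  theta_mat <- noise_matrix(n, n_ch, fs,
                            function(f) band_shape(f, 4, 8, 0.5))
  pink_mat <- noise_matrix(n, n_ch, fs, function(f) {
    s <- 1 / sqrt(pmax(f, 1)); s[f == 0] <- 0; s
  })

  X <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    # fractional-sample delay of the narrowband source (linear interpolation
    # of the analytic parts on the uniform padded grid), then slow
    # per-channel phase jitter
    base <- max_lag - lags[ch]
    fl <- floor(base); fr <- base - fl
    zs <- z_src[(fl + 1):(fl + n)] * (1 - fr) +
      z_src[(fl + 2):(fl + n + 1)] * fr
    jit <- theta_ch[ch] + jitter_sd[ch] * jit_mat[, ch]
    alpha_ch <- Re(zs) * cos(jit) - Im(zs) * sin(jit)  # Re{z e^{i(theta+jit)}}
    x <- g[ch] * amp * alpha_ch +
      theta_amp * theta_mat[, ch] +
      config$noise_sd * pink_mat[, ch]
    if (!is.null(shared_zero_lag)) x <- x + zl_gain[ch] * shared_zero_lag
    X[ch, ] <- x
  }
  X <- X * 10   # microvolt scale
  rec <- recording(X, fs = fs,
                   channel_labels = channel_labels_for(n_ch),
                   condition = condition, subject_id = subject_id)
  attr(rec, "ground_truth") <- list(f0 = f0, lags = lags, gains = g,
                                    severity = severity)
  rec
}

#' Simulate one subject's regional tau DVR profile
#'
#' \eqn{DVR_r = base_r + slope_r \cdot s + \epsilon_r},
#' \eqn{\epsilon_r \sim N(0, \sigma^2)}; the perirhinal slope is the largest
#' (earliest/steepest region) by config invariant, and all DVR are positive.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return `data.frame(region, dvr, voxel_count)`.
#' @export
simulate_tau_profile <- function(severity, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (any(config$tau_base <= 0)) stop("tau base values must be positive")
  set.seed(as.integer(seed))
  regions <- names(config$tau_base)
  dvr <- config$tau_base + config$tau_slopes[regions] * severity +
    stats::rnorm(length(regions), 0, config$tau_noise_sd)
  dvr <- pmax(dvr, 0.05)
  vox <- default_voxel_counts()
  data.frame(region = regions, dvr = unname(dvr),
             voxel_count = unname(vox[regions]),
             stringsAsFactors = FALSE)
}

#' Simulate one subject's neuropsychological test scores
#'
#' `scores = loadings %*% factors + noise`, then shifted/scaled to plausible
#' test ranges; the true factor 2-vector is the ground truth the factor
#' pipeline must recover.
#'
#' @param true_factors Length-2 vector of latent factor values.
#' @param loadings 10 x 2 loading matrix (unit-bounded entries).
#' @param noise_sd Residual standard deviation on the standardized scale.
#' @param seed Integer seed.
#' @return Named numeric vector of 10 test scores.
#' @export
simulate_neuropsych <- function(true_factors, loadings, noise_sd, seed) {
  loadings <- as.matrix(loadings)
  if (!all(dim(loadings) == c(10, 2))) stop("loadings must be 10 x 2")
  if (length(true_factors) != 2) stop("true_factors must have length 2")
  set.seed(as.integer(seed))
  z <- as.numeric(loadings %*% true_factors) + stats::rnorm(10, 0, noise_sd)
  shift <- c(AVLT_TL = 45, AVLT_DR = 80, BSRT_TR = 100, BSRT_DR = 9,
             BNT = 52, AVF = 22, LVF = 35, PALPA49 = 27, TMT_BA = 2.4,
             RPM = 45)
  scale_ <- c(AVLT_TL = 9, AVLT_DR = 15, BSRT_TR = 18, BSRT_DR = 2.2,
              BNT = 4, AVF = 5, LVF = 9, PALPA49 = 2.5, TMT_BA = 0.7,
              RPM = 8)
  out <- shift + scale_ * z
  names(out) <- rownames(loadings)
  out
}

group_label <- function(key) {
  c(cu_neg = "CU-", cu_pos = "CU+", prodromal = "prodromal")[[key]]
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Simulate a full three-group cohort
#'
#' Draws per subject: group, latent severity (uniform on the group range),
#' demographics (age, sex, education, APOE-e4; group frequencies matching the
#' emulated study design and, by default, independent of severity), an
#' amyloid tracer and Centiloid value consistent with the group (CU- below
#' the 23.5 cut-off, CU+ and prodromal above), the regional tau profile,
#' neuropsych scores from a 2-factor model whose memory factor declines with
#' severity, and (optionally kept) the EEG recordings. Everything is seeded
#' and reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param keep_recordings Keep the simulated EEG in the return value
#'   (default `TRUE`; set `FALSE` for large cohorts and regenerate per
#'   subject from `ground_truth$eeg_seed`).
#' @return List with `subjects` (one row per subject: demographics, amyloid,
#'   tau per region), `recordings` (per subject, per condition; `NULL` when
#'   dropped), and `ground_truth` (severity, true factors, eeg seeds; never
#'   consumed by the analysis stages).
#' @export
simulate_cohort <- function(config, keep_recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c("cu_neg", "cu_pos", "prodromal")
  n_tot <- sum(config$n_per_group[groups])
  ids <- sprintf("S%03d", seq_len(n_tot))

  age_par <- list(cu_neg = c(66.8, 7.0), cu_pos = c(74.2, 7.0),
                  prodromal = c(71.4, 6.5))
  p_male <- c(cu_neg = 15 / 37, cu_pos = 7 / 14, prodromal = 10 / 15)
  p_apoe <- c(cu_neg = 0.459, cu_pos = 0.786, prodromal = 0.533)
  cl_par <- list(cu_neg = c(2, 12, -30, 23.5),
                 cu_pos = c(60, 25, 23.5, 160),
                 prodromal = c(75, 30, 23.5, 180))
  tracers <- c("PiB", "NAV4694", "florbetaben")
  p_tracer <- c(0.45, 0.53, 0.02)

  rows <- list(); gt <- list(); recs <- vector("list", n_tot)
  i <- 0L
  for (gkey in groups) {
    ng <- config$n_per_group[[gkey]]
    for (s in seq_len(ng)) {
      i <- i + 1L
      sev <- stats::runif(1, config$severity_ranges[[gkey]][1],
                          config$severity_ranges[[gkey]][2])
      if (config$confound_covariates) {
        age <- rtrunc_norm(1, 62 + 14 * sev, 5, 50, 90)
      } else {
        age <- rtrunc_norm(1, age_par[[gkey]][1], age_par[[gkey]][2], 50, 90)
      }
      sex <- if (stats::runif(1) < p_male[[gkey]]) "M" else "F"
      apoe <- if (stats::runif(1) < p_apoe[[gkey]]) "carrier" else "noncarrier"
      edu <- round(rtrunc_norm(1, 17, 4, 8, 32))
      cp <- cl_par[[gkey]]
      cl <- rtrunc_norm(1, cp[1], cp[2], cp[3], cp[4])
      tracer <- sample(tracers, 1, prob = p_tracer)
      cf <- centiloid_coefs()[[tracer]]
      suvr <- (cl - cf["intercept"]) / cf["slope"]

      f1 <- -2.2 * sev + stats::rnorm(1, 0, 0.8) + 0.9
      f2 <- stats::rnorm(1, 0, 1)
      np_seed <- sample.int(.Machine$integer.max - 1L, 1)
      np <- simulate_neuropsych(c(f1, f2), config$factor_loadings,
                                config$neuropsych_noise_sd, np_seed)
      tau_seed <- sample.int(.Machine$integer.max - 1L, 1)
      tau <- simulate_tau_profile(sev, config, tau_seed)
      eeg_seeds <- stats::setNames(
        sample.int(.Machine$integer.max - 1L, length(config$conditions)),
        config$conditions)

      row <- data.frame(subject_id = ids[i], group = group_label(gkey),
                        age = age, sex = sex, apoe4 = apoe, education = edu,
                        tracer = tracer, suvr = unname(suvr),
                        cl_amyloid = cl,
                        amyloid_status = classify_amyloid(cl),
                        stringsAsFactors = FALSE)
      for (r in seq_len(nrow(tau))) {
        row[[paste0("tau_", tau$region[r])]] <- tau$dvr[r]
      }
      for (tn in names(np)) row[[tn]] <- unname(np[tn])
      rows[[i]] <- row
      gt_row <- data.frame(subject_id = ids[i], severity = sev,
                           factor_memory = f1, factor_language = f2,
                           stringsAsFactors = FALSE)
      for (cond in names(eeg_seeds)) {
        gt_row[[paste0("eeg_seed_", cond)]] <- unname(eeg_seeds[[cond]])
      }
      gt[[i]] <- gt_row
      if (keep_recordings) {
        recs[[i]] <- lapply(stats::setNames(config$conditions,
                                            config$conditions),
                            function(cond) {
          simulate_subject_eeg(config, sev, eeg_seeds[[cond]],
                               condition = cond, subject_id = ids[i])
        })
      }
    }
  }
  subjects <- do.call(rbind, rows)
  ground_truth <- do.call(rbind, gt)
  list(subjects = subjects,
       recordings = if (keep_recordings) stats::setNames(recs, ids) else NULL,
       ground_truth = ground_truth,
       config = config)
}

#' Write cohort tables (and optionally EDF recordings) to disk
#'
#' Writes `cohort.tsv` (demographics + amyloid + per-region tau + neuropsych;
#' severity withheld), `ground_truth.tsv` (the latent variables, for recovery
#' tests only), a YAML config snapshot with the explicit seed, and one EDF
#' file per subject/condition when recordings are present.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_edf_files Write per-subject EDF recordings (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_edf_files = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  snap <- cfg[c("duration_s", "fs", "n_channels", "coupling_base",
                "coupling_slope", "alpha_amp", "theta_amp", "theta_slope",
                "noise_sd", "zero_lag_gain", "tau_noise_sd",
                "neuropsych_noise_sd", "seed")]
  snap$n_per_group <- as.list(cfg$n_per_group)
  snap$severity_ranges <- lapply(cfg$severity_ranges, as.numeric)
  snap$conditions <- cfg$conditions
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  if (write_edf_files && !is.null(cohort$recordings)) {
    for (sid in names(cohort$recordings)) {
      for (cond in names(cohort$recordings[[sid]])) {
        rec <- cohort$recordings[[sid]][[cond]]
        if (!is.null(rec)) {
          write_edf(rec, file.path(dir, sprintf("%s_%s.edf", sid, cond)))
        }
      }
    }
  }
  invisible(dir)
}
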