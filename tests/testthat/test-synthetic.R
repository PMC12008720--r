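test_that("config validation guards the study-design invariants", {
  expect_s3_class(small_config(), "cohort_config")
  expect_error(small_config(duration_s = 70), ">= 80")
  expect_error(small_config(n_per_group = c(cu_neg = 0L, cu_pos = 1L,
                                            prodromal = 1L)), "n >= 1")
  expect_error(small_config(
    severity_ranges = list(cu_neg = c(0, 1.4), cu_pos = c(0, 1),
                           prodromal = c(0, 1))), "within")
  bad_slopes <- c(entorhinal = 2, perirhinal = 0.8,
                  hippocampus_caudal = 0.5, hippocampus_rostral = 0.5,
                  parahippocampus_lateral = 0.5,
                  parahippocampus_medial = 0.5, fusiform = 0.6,
                  temporal_inferior = 0.4, temporal_lateral = 0.4,
                  parietal_inferior = 0.3, parietal_medial = 0.3)
  expect_error(small_config(tau_slopes = bad_slopes), "perirhinal")
})

test_that("EEG simulation is bit-deterministic and validates inputs", {
  cfg <- small_config(duration_s = 80)
  a <- simulate_subject_eeg(cfg, 0.4, seed = 9)
  b <- simulate_subject_eeg(cfg, 0.4, seed = 9)
  expect_identical(a$samples, b$samples)
  c_ <- simulate_subject_eeg(cfg, 0.4, seed = 10)
  expect_false(identical(a$samples, c_$samples))
  expect_error(simulate_subject_eeg(cfg, 1.3, seed = 1), "\\[0, 1\\]")
  gt <- attr(a, "ground_truth")
  expect_true(all(gt$lags >= 1 & gt$lags <= 4))
  expect_true(all(gt$gains > 0))
})

test_that("uncoupled channels sit at the wPLI null, coupled ones far above", {
  cfg0 <- small_config(coupling_base = 0, duration_s = 80, n_channels = 4)
  rec0 <- simulate_subject_eeg(cfg0, 0, seed = 11)
  adj0 <- recording_to_adjacency(rec0, analysis_fs = 128)
  expect_lt(mean(adj0$W[upper.tri(adj0$W)]), 0.3)   # null scale, not ~1
  cfg1 <- small_config(duration_s = 80, n_channels = 4,
                       subject_jitter_sd = 0)
  rec1 <- simulate_subject_eeg(cfg1, 0, seed = 11)
  adj1 <- recording_to_adjacency(rec1, analysis_fs = 128)
  expect_gt(mean(adj1$W[upper.tri(adj1$W)]), 0.5)
})

test_that("the slowing effect: theta/alpha ratio grows with severity", {
  cfg <- small_config(duration_s = 80, n_channels = 4)
  ratio <- function(sev, seed) {
    rec <- simulate_subject_eeg(cfg, sev, seed)
    ps <- welch_psd(epoch_recording(rec, 60, 20))
    mean(relative_band_power(ps, c(4, 8)) /
           relative_band_power(ps, c(8, 13)))
  }
  seeds <- 1:20
  r0 <- mean(sapply(seeds, function(s) ratio(0, s)))
  r1 <- mean(sapply(seeds, function(s) ratio(1, s + 1000)))
  expect_gt(r1, r0)
})

test_that("zero-lag mixing does not inflate wPLI above the null band", {
  # confound switch on, no genuine coupling: the shared instantaneous
  # component must stay invisible to wPLI
  cfg_mix <- small_config(coupling_base = 0, zero_lag_gain = 2,
                          duration_s = 80, n_channels = 4)
  cfg_null <- small_config(coupling_base = 0, duration_s = 80,
                           n_channels = 4)
  w_mix <- sapply(1:12, function(s) {
    adj <- recording_to_adjacency(
      simulate_subject_eeg(cfg_mix, 0, s), analysis_fs = 128)
    mean(adj$W[upper.tri(adj$W)])
  })
  w_null <- sapply(101:130, function(s) {
    adj <- recording_to_adjacency(
      simulate_subject_eeg(cfg_null, 0, s), analysis_fs = 128)
    mean(adj$W[upper.tri(adj$W)])
  })
  expect_lt(mean(w_mix), quantile(w_null, 0.95) + 0.05)
  # ... while plain amplitude correlation DOES inflate under the mixing
  rec <- simulate_subject_eeg(cfg_mix, 0, 7)
  cc <- cor(t(rec$samples))
  expect_gt(mean(abs(cc[upper.tri(cc)])), 0.3)
})

test_that("tau profiles follow base + slope * severity with positive DVR", {
  cfg <- small_config(tau_noise_sd = 0)
  prof0 <- simulate_tau_profile(0, cfg, seed = 12)
  expect_equal(stats::setNames(prof0$dvr, prof0$region),
               cfg$tau_base[prof0$region])
  prof1 <- simulate_tau_profile(1, cfg, seed = 12)
  expect_equal(prof1$dvr - prof0$dvr,
               unname(cfg$tau_slopes[prof0$region]))
  expect_true(all(prof1$dvr > 0))
  # perirhinal pulls ahead of entorhinal linearly in severity
  d_at <- function(s) {
    p <- simulate_tau_profile(s, cfg, seed = 1)
    p$dvr[p$region == "perirhinal"] - p$dvr[p$region == "entorhinal"]
  }
  expect_gt(d_at(0.8), d_at(0.4))
  expect_gt(d_at(0.4), d_at(0))
})

test_that("group means of early-metaVOI tau order CU- < CU+ < prodromal", {
  cfg <- small_config(n_per_group = c(cu_neg = 50L, cu_pos = 50L,
                                      prodromal = 50L))
  voi <- voi_definition("early_metaVOI")
  means <- sapply(c("cu_neg", "cu_pos", "prodromal"), function(g) {
    mean(sapply(1:20, function(s) {
      set.seed(s * 100)
      sev <- runif(1, cfg$severity_ranges[[g]][1],
                   cfg$severity_ranges[[g]][2])
      aggregate_voi(simulate_tau_profile(sev, cfg, seed = s), voi)
    }))
  })
  expect_lt(means["cu_neg"], means["cu_pos"])
  expect_lt(means["cu_pos"], means["prodromal"])
})

test_that("neuropsych scores embed the 2-factor structure", {
  L <- default_factor_loadings()
  sc <- simulate_neuropsych(c(1, -1), L, noise_sd = 0, seed = 13)
  expect_length(sc, 10)
  expect_named(sc, rownames(L))
  expect_error(simulate_neuropsych(c(1, 2, 3), L, 0.1, 1), "length 2")
  expect_error(simulate_neuropsych(c(1, 2), L[1:5, ], 0.1, 1), "10 x 2")
  # noiseless scores across subjects have correlation rank <= 2
  X <- t(sapply(1:60, function(i) {
    simulate_neuropsych(rnorm(2), L, noise_sd = 0, seed = i)
  }))
  ev <- eigen(cor(X), only.values = TRUE)$values
  expect_lt(ev[3] / ev[1], 1e-8)
})

test_that("cohort assembly matches the three-group study design", {
  cfg <- small_config(n_per_group = c(cu_neg = 37L, cu_pos = 14L,
                                      prodromal = 15L))
  coh <- simulate_cohort(cfg, keep_recordings = FALSE)
  expect_identical(nrow(coh$subjects), 66L)
  expect_equal(as.numeric(table(coh$subjects$group)[c("CU-", "CU+",
                                                      "prodromal")]),
               c(37, 14, 15))
  # amyloid status consistent with group
  expect_true(all(coh$subjects$cl_amyloid[coh$subjects$group == "CU-"] <
                    23.5))
  expect_true(all(coh$subjects$cl_amyloid[coh$subjects$group != "CU-"] >
                    23.5))
  # Centiloid column is consistent with the tracer-specific map of suvr
  cl_back <- suvr_to_centiloid(coh$subjects$suvr, coh$subjects$tracer)
  expect_equal(cl_back, coh$subjects$cl_amyloid, tolerance = 1e-9)
  # severity stays in the group ranges
  gt <- merge(coh$ground_truth, coh$subjects[, c("subject_id", "group")])
  for (g in c("CU-", "CU+", "prodromal")) {
    key <- c("CU-" = "cu_neg", "CU+" = "cu_pos",
             "prodromal" = "prodromal")[[g]]
    rg <- cfg$severity_ranges[[key]]
    sev <- gt$severity[gt$group == g]
    expect_true(all(sev >= rg[1] & sev <= rg[2]))
  }
})

test_that("identical seeds give byte-identical serialized cohorts", {
  cfg <- small_config(n_per_group = c(cu_neg = 2L, cu_pos = 1L,
                                      prodromal = 1L), duration_s = 80,
                      n_channels = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("generator internals encode the monotone severity effects", {
  cfg <- small_config(duration_s = 80, n_channels = 6)
  gains <- sapply(c(0, 0.5, 1), function(sev) {
    mean(sapply(1:10, function(s) {
      mean(attr(simulate_subject_eeg(cfg, sev, s), "ground_truth")$gains)
    }))
  })
  expect_true(all(diff(gains) < 0))   # coupling strictly decreasing
})

test_that("cohort writer emits the TSV/YAML layout with severity withheld", {
  cfg <- small_config(n_per_group = c(cu_neg = 2L, cu_pos = 1L,
                                      prodromal = 1L), duration_s = 80,
                      n_channels = 4)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, write_edf_files = TRUE)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  tab <- read.delim(file.path(dir, "cohort.tsv"))
  expect_false("severity" %in% names(tab))
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_true("severity" %in% names(gt))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg_back$seed, cfg$seed)
  edfs <- list.files(dir, pattern = "\\.edf$")
  expect_length(edfs, 4)
  rec <- read_edf(file.path(dir, edfs[1]))
  expect_identical(nrow(rec$samples), 4L)
})
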